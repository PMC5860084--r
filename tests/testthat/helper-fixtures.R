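# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures are stored.

# A minimal MEDLINE/PubMed XML file: 3 articles, one without an abstract,
# one with 4 MeSH descriptors, one with 2 chemicals.
write_medline_fixture <- function(path) {
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<PubmedArticleSet>",
    "<PubmedArticle><MedlineCitation><PMID>1001</PMID>",
    "<Article><ArticleTitle>First</ArticleTitle>",
    "<Abstract><AbstractText>P53 induces apoptosis. Tumor growth was reduced.</AbstractText></Abstract>",
    "</Article>",
    "<MeshHeadingList>",
    "<MeshHeading><DescriptorName>Lung Neoplasms</DescriptorName></MeshHeading>",
    "<MeshHeading><DescriptorName>Apoptosis</DescriptorName></MeshHeading>",
    "<MeshHeading><DescriptorName>Humans</DescriptorName></MeshHeading>",
    "<MeshHeading><DescriptorName>Mice</DescriptorName></MeshHeading>",
    "</MeshHeadingList>",
    "</MedlineCitation></PubmedArticle>",
    "<PubmedArticle><MedlineCitation><PMID>1002</PMID>",
    "<Article><ArticleTitle>No abstract here</ArticleTitle></Article>",
    "</MedlineCitation></PubmedArticle>",
    "<PubmedArticle><MedlineCitation><PMID>1003</PMID>",
    "<Article><ArticleTitle>Third</ArticleTitle>",
    "<Abstract><AbstractText>Cisplatin blocks DNA repair, i.e. strand breaks persist.</AbstractText></Abstract>",
    "</Article>",
    "<ChemicalList>",
    "<Chemical><NameOfSubstance>Cisplatin</NameOfSubstance></Chemical>",
    "<Chemical><NameOfSubstance>Aspirin</NameOfSubstance></Chemical>",
    "</ChemicalList>",
    "</MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>")
  writeLines(xml, path)
  path
}

# Annotated-corpus TSV content as a character vector of lines.
annotated_fixture_lines <- function() {
  c("pmid\tsent_index\tlabels\ttext",
    "2001\t0\t3|3.1\tcaspase activation drives apoptosis",
    "2001\t1\t\tthe assay was repeated twice",
    "2002\t0\t7.1.2\tgamma irradiation produced strand breaks",
    "2002\t1\tApoptosis\tcells died by programmed death")
}

# Hand-built sentence corpus from parallel vectors (tokens = words of text).
make_corpus <- function(pmid, text, gold = NULL, mesh = NULL, chem = NULL) {
  n <- length(text)
  tok <- lapply(text, default_tokenizer)
  empty <- rep(list(character(0)), n)
  hallmarker:::new_corpus(
    pmid = pmid,
    sent_index = unlist(lapply(table(factor(pmid, levels = unique(pmid))),
                               function(k) seq_len(k) - 1L)),
    text = text, tokens = tok, lemmas = lapply(tok, tolower),
    mesh = if (is.null(mesh)) empty else mesh,
    chem = if (is.null(chem)) empty else chem,
    gold = if (is.null(gold)) empty else gold)
}

# Tiny two-class embedding with hand-set vectors for SD feature tests.
toy_embedding <- function() {
  wv <- rbind(wa = c(1, 0), wb = c(0, 1), wz = c(0, 0))
  lv <- rbind(`1` = c(1, 0), `2` = c(0, 1))
  structure(list(dimension = 2L, word_vectors = wv, label_vectors = lv,
                 config = list(method = "fixture")),
            class = "hoc_embedding")
}

# Confusion counts of predictions vs hypernym-closed gold for one node.
node_confusion <- function(preds, gold_closed, code) {
  truth <- vapply(gold_closed, function(g) code %in% g, logical(1))
  pred <- vapply(preds$final, function(g) code %in% g, logical(1))
  c(tp = sum(pred & truth), fp = sum(pred & !truth),
    tn = sum(!pred & !truth), fn = sum(!pred & truth))
}
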