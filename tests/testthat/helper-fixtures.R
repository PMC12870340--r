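# Small handmade fixtures shared across tests.

# chain R <- G <- P <- L plus a deprecated alias and a diamond
#   L2 -> {P, P2}, P2 -> G  (two paths from L2 to G)
toy_taxonomy <- function() {
  taxonomy(list(
    list(code = "R", preferred_label = "rare disease group"),
    list(code = "G", preferred_label = "storage disorder", parents = "R"),
    list(code = "P", preferred_label = "lipid storage disorder",
         parents = "G"),
    list(code = "P2", preferred_label = "sphingolipidosis", parents = "G"),
    list(code = "L", preferred_label = "Gaucher disease",
         synonyms = c("glucocerebrosidase deficiency", "GD"), parents = "P"),
    list(code = "L2", preferred_label = "Niemann-Pick disease type B",
         parents = c("P", "P2")),
    list(code = "OLD", preferred_label = "beta thalassemia major",
         status = "deprecated", replaced_by = "L2"),
    list(code = "OLD2", preferred_label = "historic label",
         status = "deprecated", replaced_by = "OLD")
  ), version_tag = "toy")
}

toy_dictionary <- function(tax = toy_taxonomy(), ...) {
  build_dictionary(tax, ...)
}

toy_record <- function(doc_id = "d1",
                       title = "A study of Gaucher disease",
                       abstract = "We discuss lipid storage disorder cases.",
                       keywords = c("sphingolipidosis")) {
  article_record(doc_id, title, abstract, keywords)
}
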