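Full yeast data set (not redistributed with the package)
=========================================================

The full-scale yeast analysis needs four plain TSV files in this directory.
They are derived from public resources (STRING yeast functional-association
network at highest confidence, CYGD phenotype annotations, CYGD complex
memberships, KEGG pathway memberships) and are not shipped here; convert
them once with any PDF/table extraction tool into the layouts below.

network.tsv      protein_a <TAB> protein_b <TAB> combined_score
                 (integer confidence 0-999; header optional)
annotations.tsv  protein <TAB> comma-separated category indices 1-11
complexes.tsv    protein <TAB> comma-separated complex IDs
pathways.tsv     protein <TAB> comma-separated pathway IDs
                 (the literal token "no annotation" flags proteins without
                 membership)

With these present, the full analysis is e.g.:

  net <- read_edge_list("network.tsv", min_weight = 900)
  ann <- read_annotations("annotations.tsv", yeast_phenotype_scheme())
  ev  <- evaluate_predictor(net, ann, yeast_phenotype_scheme(), seed = 1)
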