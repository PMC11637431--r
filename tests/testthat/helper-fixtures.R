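# In-code fixtures for paired LCM designs.

# Metadata for a full subjects x zones x compartments design.
paired_meta <- function(n_subjects, species = "human",
                        zones = c("tip", "base"), prefix = "S") {
  g <- expand.grid(
    compartment = c("apical", "basal"), zone = zones,
    subject = paste0(prefix, seq_len(n_subjects)),
    stringsAsFactors = FALSE
  )
  g$species <- species
  g$sample_id <- paste(g$subject, g$zone, g$compartment, sep = "_")
  g[, c("sample_id", "subject", "species", "compartment", "zone")]
}

# Count matrix from a generator function f(sample_row) -> integer vector.
build_counts <- function(n_genes, meta, f) {
  vals <- vapply(seq_len(nrow(meta)), function(j) as.integer(f(meta[j, ])),
                 integer(n_genes))
  vals <- matrix(vals, nrow = n_genes)
  rownames(vals) <- sprintf("g%03d", seq_len(n_genes))
  colnames(vals) <- meta$sample_id
  count_matrix(vals, meta)
}

# Small protein table fixture.
build_protein_table <- function(values, n_subjects = 2,
                                unique_peptides = NULL, contaminant = NULL) {
  meta <- paired_meta(n_subjects, prefix = "P")
  stopifnot(ncol(values) == nrow(meta))
  colnames(values) <- meta$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("prot%03d", seq_len(nrow(values)))
  }
  if (is.null(unique_peptides)) unique_peptides <- rep(5L, nrow(values))
  if (is.null(contaminant)) contaminant <- rep(FALSE, nrow(values))
  protein_table(values, meta, unique_peptides, contaminant)
}
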