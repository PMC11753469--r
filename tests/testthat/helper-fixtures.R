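# Shared fixture builders (all data generated in code).

# A gene_weight_table built directly from a named weight vector.
.mock_weights <- function(w, model_id = "model1", environment = "e") {
  structure(
    data.frame(gene = names(w), lps_class = gene_class(names(w)),
               weight = as.numeric(w), stringsAsFactors = FALSE),
    model_id = model_id, environment = environment, total_weight = sum(w),
    class = c("gene_weight_table", "data.frame"))
}

# Write a counts CSV (environment, count, Nt, epsilon) and return its path.
.write_counts_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("environment,count,Nt,epsilon", rows), path)
  path
}
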