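# wrap a plain symmetric matrix as the package's distance container
distance_matrix_for_test <- function(m, metric = "euclidean") {
  soilgv:::distance_matrix(m, metric)
}
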