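# CSV input goes through base R's parser: unlike fast approximate float
# parsers it is correctly rounded, so tables written with full shortest
# round-trip precision read back bit-exactly.
read_csv_exact <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "npqkit_schema_error")
  }
  tibble::as_tibble(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  )
}
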