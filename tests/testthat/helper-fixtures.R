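# fixtures are built in code; nothing binary ships with the tests

write_amplitude_csv <- function(ch1, ch2, headers = c("Ch1 Amplitude", "Ch2 Amplitude"),
                                path = withr::local_tempfile(fileext = ".csv",
                                                             .local_envir = parent.frame())) {
  lines <- c(paste(headers, collapse = ","),
             if (length(ch1) > 0) paste(ch1, ch2, sep = ","))
  writeLines(lines, path)
  path
}

write_tsv <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                       .local_envir = parent.frame())) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

write_bed <- function(chrom, start0, end0,
                      path = withr::local_tempfile(fileext = ".bed",
                                                   .local_envir = parent.frame())) {
  writeLines(paste(chrom, start0, end0, sep = "\t"), path)
  path
}

# one well-formed candidate that passes every filter against test_resources()
base_candidate <- function(...) {
  args <- list(gene5 = "ETV6", gene3 = "NTRK3",
               contig5 = "chr12", pos5 = 150L,
               contig3 = "chr15", pos3 = 1150L,
               reads5 = 23L, reads3 = 23L, homology = 5L)
  args[names(list(...))] <- list(...)
  do.call(fusion_candidates, args)
}

# capture: chr12:100-200 and chr15:1100-1200 (BED, 0-based half-open);
# blocklist position chr1:5000; blocklist pair FGFR3|TACC3
test_resources <- function(env = parent.frame()) {
  bed <- write_bed(c("chr12", "chr15"), c(100L, 1100L), c(200L, 1200L),
                   path = withr::local_tempfile(fileext = ".bed", .local_envir = env))
  filter_resources(
    load_capture_bed(bed),
    blocklist_positions = data.frame(contig = "chr1", position = 5000L),
    blocklist_pairs = data.frame(gene_a = "FGFR3", gene_b = "TACC3"))
}

# the bundled detected-sample table (16 rows with printed VAFs and counts)
detected_table <- function() {
  read.delim(system.file("extdata", "detected_samples.tsv", package = "ddctdna"),
             check.names = TRUE)
}

# independent Monte-Carlo oracle: scatter `copies` template molecules over
# `n` droplets uniformly at random, return the number of occupied droplets
mc_positive_droplets <- function(copies, n) {
  if (copies == 0) return(0L)
  length(unique(sample.int(n, size = copies, replace = TRUE)))
}
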