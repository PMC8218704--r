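# Post-filtering of structural-variant fusion candidates from a capture
# panel. An SV caller's raw candidate list is noisy; the filter chain
# removes candidates with weak read support, breakpoints off-panel at both
# ends, recurrent false-positive breakpoints or gene pairs, intragenic
# events, and long microhomology at the junction (a hallmark of alignment
# artifacts).

FUSION_RULES <- c("read_support", "capture_membership", "blocklisted_position",
                  "blocklisted_pair", "intragenic", "homology")

#' Load and merge a capture-region BED file
#'
#' Reads a BED3+ file of capture-probe target intervals, merging overlaps.
#' Intervals are half-open and 0-based on disk (BED convention) and are
#' kept that way internally; [capture_contains] is the single place where
#' 1-based candidate positions meet these intervals. Membership is
#' half-open: a 1-based position `p` is inside an interval `[start, end)`
#' iff `start <= p < end` — so a position equal to the BED end coordinate
#' is outside.
#'
#' @param path Path to a BED file (at least chrom, start, end columns).
#' @return A `capture_set`: data.frame with columns `chrom`, `start0`,
#'   `end0` (sorted, merged).
#' @export
load_capture_bed <- function(path) {
  if (!file.exists(path))
    ddctdna_error(sprintf("capture BED not found: %s", path), "ddctdna_io_error")
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t")[[1]]
    ok <- length(f) >= 3 &&
      !is.na(suppressWarnings(s <- as.numeric(f[2]))) &&
      !is.na(suppressWarnings(e <- as.numeric(f[3]))) && s < e
    if (!ok)
      ddctdna_error(sprintf("malformed BED line %d in %s", i, path),
                    "ddctdna_format_error")
  }
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  structure(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,  # back to BED coordinates
    end0 = GenomicRanges::end(gr)),
    class = c("capture_set", "data.frame"))
}

#' Capture-set membership of 1-based positions
#'
#' @param capture A `capture_set` from [load_capture_bed] (or a data.frame
#'   with `chrom`, `start0`, `end0`).
#' @param contig Character vector of contig names.
#' @param pos Integer vector of 1-based positions.
#' @return Logical vector; positions on contigs absent from the capture
#'   reference are `FALSE` (treated as outside).
#' @export
capture_contains <- function(capture, contig, pos) {
  mapply(function(ctg, p) {
    any(capture$chrom == ctg & capture$start0 <= p & p < capture$end0)
  }, contig, pos, USE.NAMES = FALSE)
}

#' Bundle the filter resources
#'
#' @param capture A `capture_set` ([load_capture_bed]).
#' @param blocklist_positions Data.frame with columns `contig`, `position`
#'   (1-based) of recurrent false-positive breakpoints; may have 0 rows.
#' @param blocklist_pairs Data.frame with columns `gene_a`, `gene_b` of
#'   recurrent false-positive gene pairs (unordered); may have 0 rows.
#' @return A `filter_resources` object.
#' @export
filter_resources <- function(capture,
                             blocklist_positions = data.frame(contig = character(),
                                                              position = integer()),
                             blocklist_pairs = data.frame(gene_a = character(),
                                                          gene_b = character())) {
  stopifnot(all(c("chrom", "start0", "end0") %in% names(capture)),
            all(c("contig", "position") %in% names(blocklist_positions)),
            all(c("gene_a", "gene_b") %in% names(blocklist_pairs)))
  if (nrow(capture) > 0 && any(capture$start0 >= capture$end0))
    ddctdna_error("capture intervals must satisfy start < end", "ddctdna_validation_error")
  structure(list(capture = capture,
                 blocklist_positions = blocklist_positions,
                 blocklist_pairs = blocklist_pairs),
            class = "filter_resources")
}

#' Read fusion candidates from a BEDPE-like TSV
#'
#' Expected columns: `chrom1, start1, end1, chrom2, start2, end2, gene5,
#' gene3, reads5, reads3, homology`. Starts/ends are 0-based half-open
#' (BEDPE convention); the candidate's 1-based breakpoint is `start + 1`.
#'
#' @param path Path to the TSV.
#' @return Data.frame of candidates with 1-based `pos5`/`pos3` columns.
#' @export
read_fusion_candidates <- function(path) {
  if (!file.exists(path))
    ddctdna_error(sprintf("candidate file not found: %s", path), "ddctdna_io_error")
  df <- read.delim(path, check.names = TRUE)
  need <- c("chrom1", "start1", "chrom2", "start2", "gene5", "gene3",
            "reads5", "reads3", "homology")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    ddctdna_error(sprintf("candidate table is missing column(s): %s",
                          paste(miss, collapse = ", ")), "ddctdna_format_error")
  fusion_candidates(gene5 = df$gene5, gene3 = df$gene3,
                    contig5 = df$chrom1, pos5 = df$start1 + 1L,
                    contig3 = df$chrom2, pos3 = df$start2 + 1L,
                    reads5 = df$reads5, reads3 = df$reads3,
                    homology = df$homology)
}

#' Construct a fusion-candidate table
#'
#' @param gene5,gene3 Gene symbols at the 5' and 3' side of the junction.
#' @param contig5,pos5 Contig and 1-based breakpoint of the 5' side.
#' @param contig3,pos3 Contig and 1-based breakpoint of the 3' side.
#' @param reads5,reads3 Reads covering each gene across the junction.
#' @param homology Junction microhomology length in bp.
#' @return Data.frame of class `fusion_candidates`.
#' @export
fusion_candidates <- function(gene5, gene3, contig5, pos5, contig3, pos3,
                              reads5, reads3, homology) {
  df <- data.frame(gene5 = as.character(gene5), gene3 = as.character(gene3),
                   contig5 = as.character(contig5), pos5 = as.integer(pos5),
                   contig3 = as.character(contig3), pos3 = as.integer(pos3),
                   reads5 = as.integer(reads5), reads3 = as.integer(reads3),
                   homology = as.integer(homology))
  if (nrow(df) > 0 &&
      (any(df$pos5 < 1) || any(df$pos3 < 1) || any(df$reads5 < 0) ||
       any(df$reads3 < 0) || any(df$homology < 0)))
    ddctdna_error("positions must be >= 1 and counts/homology non-negative",
                  "ddctdna_validation_error")
  structure(df, class = c("fusion_candidates", "data.frame"))
}

#' Filter fusion candidates by the panel's rule chain
#'
#' A candidate is rejected if ANY rule fires:
#' \describe{
#'   \item{read_support}{fewer than `min_reads` reads covering either gene
#'     (default 3, i.e. "more than 2 reads" on both genes, strictly).}
#'   \item{capture_membership}{BOTH breakpoints fall outside the capture
#'     set (one targeted end suffices to keep, as in capture-bait designs
#'     where only one partner is baited).}
#'   \item{blocklisted_position}{either breakpoint lies within
#'     `bp_tolerance` bp (default 10, inclusive) of a recurrent
#'     false-positive breakpoint.}
#'   \item{blocklisted_pair}{the unordered gene pair is a recurrent false
#'     positive.}
#'   \item{intragenic}{both partners are the same gene.}
#'   \item{homology}{junction microhomology exceeds `max_homology` bp
#'     (default 10, strict).}
#' }
#'
#' @param candidates A [fusion_candidates] data.frame.
#' @param resources A [filter_resources].
#' @param min_reads Minimum reads covering each gene; default 3.
#' @param max_homology Maximum junction homology in bp; default 10.
#' @param bp_tolerance Blocklist position tolerance in bp; default 10.
#' @return List with `retained` (candidates plus a `passed_filters` column
#'   listing all six rule tags) and `rejected` (candidates plus `reason`,
#'   the first failing rule, and `failed_rules`, all failing rules,
#'   comma-separated).
#' @export
filter_candidates <- function(candidates, resources, min_reads = 3,
                              max_homology = 10, bp_tolerance = 10) {
  stopifnot(inherits(resources, "filter_resources"))
  n <- nrow(candidates)
  fails <- matrix(FALSE, nrow = n, ncol = length(FUSION_RULES),
                  dimnames = list(NULL, FUSION_RULES))
  if (n > 0) {
    fails[, "read_support"] <-
      candidates$reads5 < min_reads | candidates$reads3 < min_reads
    in5 <- capture_contains(resources$capture, candidates$contig5, candidates$pos5)
    in3 <- capture_contains(resources$capture, candidates$contig3, candidates$pos3)
    fails[, "capture_membership"] <- !in5 & !in3
    near_block <- function(ctg, p) {
      bl <- resources$blocklist_positions
      if (nrow(bl) == 0) return(rep(FALSE, length(p)))
      mapply(function(cc, pp)
        any(bl$contig == cc & abs(bl$position - pp) <= bp_tolerance),
        ctg, p, USE.NAMES = FALSE)
    }
    fails[, "blocklisted_position"] <-
      near_block(candidates$contig5, candidates$pos5) |
      near_block(candidates$contig3, candidates$pos3)
    pair_key <- function(a, b)
      paste(pmin(as.character(a), as.character(b)),
            pmax(as.character(a), as.character(b)), sep = "|")
    bp <- resources$blocklist_pairs
    fails[, "blocklisted_pair"] <- if (nrow(bp) > 0)
      pair_key(candidates$gene5, candidates$gene3) %in%
        pair_key(bp$gene_a, bp$gene_b) else FALSE
    fails[, "intragenic"] <- candidates$gene5 == candidates$gene3
    fails[, "homology"] <- candidates$homology > max_homology
  }
  rejected_idx <- which(rowSums(fails) > 0)
  retained_idx <- setdiff(seq_len(n), rejected_idx)
  retained <- candidates[retained_idx, , drop = FALSE]
  if (nrow(retained) > 0)
    retained$passed_filters <- paste(FUSION_RULES, collapse = ",")
  rejected <- candidates[rejected_idx, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- apply(fails[rejected_idx, , drop = FALSE], 1,
                             function(f) FUSION_RULES[which(f)[1]])
    rejected$failed_rules <- apply(fails[rejected_idx, , drop = FALSE], 1,
                                   function(f) paste(FUSION_RULES[f], collapse = ","))
  }
  list(retained = retained, rejected = rejected)
}
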