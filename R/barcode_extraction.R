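# Anchored barcode extraction from amplicon reads and bounded-mismatch
# assignment to promoters. The amplicon places a constant anchor sequence
# immediately 5' of the 15-nt barcode (and optionally a constant 3'
# anchor); the exact anchor sequences are configuration, not constants,
# because they depend on the library's cloning context.

#' Amplicon layout and matching configuration
#'
#' Describes where the barcode sits inside each read and how tolerant
#' extraction and assignment are. Defaults allow one substitution in each
#' anchor and one in the barcode, which tolerates typical sequencer error
#' without inflating cross-talk between barcodes; the single-read layout is
#' in a fixed orientation, so reverse-complement search is off by default.
#'
#' @param anchor5 constant sequence immediately 5' of the barcode (required,
#'   non-empty).
#' @param anchor3 constant sequence immediately 3' of the barcode, or `""`
#'   to skip the 3' check.
#' @param bc_length barcode length (default 15).
#' @param max_anchor_mismatch maximum substitutions tolerated in each anchor.
#' @param max_bc_mismatch maximum substitutions tolerated when assigning an
#'   observed barcode to the map.
#' @param search_revcomp also try the reverse complement of reads that fail
#'   in the forward orientation.
#' @return An `amplicon_config` list.
#' @export
amplicon_config <- function(anchor5, anchor3 = "", bc_length = 15L,
                            max_anchor_mismatch = 1L, max_bc_mismatch = 1L,
                            search_revcomp = FALSE) {
  anchor5 <- toupper(anchor5)
  anchor3 <- toupper(anchor3)
  if (!nzchar(anchor5)) stop("anchor5 must be non-empty")
  if (grepl("[^ACGT]", anchor5) || grepl("[^ACGT]", anchor3)) {
    stop("anchors must be ACGT sequences")
  }
  stopifnot(is_count(bc_length),
            max_anchor_mismatch >= 0, max_bc_mismatch >= 0)
  structure(list(anchor5 = anchor5, anchor3 = anchor3,
                 bc_length = as.integer(bc_length),
                 max_anchor_mismatch = as.integer(max_anchor_mismatch),
                 max_bc_mismatch = as.integer(max_bc_mismatch),
                 search_revcomp = isTRUE(search_revcomp)),
            class = "amplicon_config")
}

# Vectorized anchored extraction. Returns a character vector with
# NA_character_ where no acceptable placement exists. Placement rule:
# the anchor5 position with the fewest mismatches (<= max_anchor_mismatch),
# ties broken leftmost, is located first; the barcode window and, if
# configured, the 3' anchor are then validated at that single position
# (no backtracking to worse-scoring placements).
extract_barcodes_vec <- function(seqs, config) {
  stopifnot(inherits(config, "amplicon_config"))
  n <- length(seqs)
  if (n == 0L) return(character(0))
  seqs <- toupper(seqs)
  out <- rep(NA_character_, n)

  la <- nchar(config$anchor5)
  l3 <- nchar(config$anchor3)
  bcl <- config$bc_length

  locate_anchor <- function(sq) {
    # best-scoring leftmost anchor5 start per read, NA if none admissible
    pos <- rep(NA_integer_, length(sq))
    dss <- Biostrings::DNAStringSet(sq)
    for (m in 0:config$max_anchor_mismatch) {
      todo <- which(is.na(pos))
      if (!length(todo)) break
      hits <- Biostrings::vmatchPattern(config$anchor5, dss[todo],
                                        max.mismatch = m, fixed = TRUE)
      starts <- Biostrings::startIndex(hits)
      first <- vapply(starts, function(v) {
        if (is.null(v) || length(v) == 0L) NA_integer_ else v[[1L]]
      }, integer(1))
      pos[todo] <- first
    }
    pos
  }

  resolve <- function(sq) {
    res <- rep(NA_character_, length(sq))
    pos <- locate_anchor(sq)
    ok <- !is.na(pos)
    if (!any(ok)) return(res)
    bc_start <- pos + la
    bc <- substr(sq, bc_start, bc_start + bcl - 1L)
    ok <- ok & !is.na(bc) & nchar(bc) == bcl
    if (l3 > 0L && any(ok)) {
      a3_start <- bc_start + bcl
      a3 <- substr(sq, a3_start, a3_start + l3 - 1L)
      full <- nchar(a3) == l3
      ok <- ok & full
      idx <- which(ok)
      if (length(idx)) {
        a3m <- char_matrix(a3[idx])
        ref <- strsplit(config$anchor3, "", fixed = TRUE)[[1L]]
        mm <- colSums(a3m != ref)
        ok[idx] <- mm <= config$max_anchor_mismatch
      }
    }
    res[ok] <- bc[ok]
    res
  }

  out <- resolve(seqs)
  if (config$search_revcomp && anyNA(out)) {
    failed <- which(is.na(out))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[failed])))
    out[failed] <- resolve(rc)
  }
  out
}

#' Extract the barcode from one amplicon read
#'
#' Locates the 5' anchor at its best-scoring (fewest mismatches, ties
#' broken leftmost) admissible position and returns the following
#' `bc_length` bases. If a 3' anchor is configured it must follow the
#' barcode within the anchor mismatch limit. Returns `NA` when no
#' acceptable placement exists or the barcode window runs off the read end;
#' per-read failures are tallies, never errors.
#'
#' @param read_sequence a read as a character scalar.
#' @param config an [amplicon_config()].
#' @return The barcode string, or `NA_character_`.
#' @examples
#' cfg <- amplicon_config("ACGTACGT", bc_length = 4)
#' extract_barcode("ACGTACGTTTTTGG", cfg)
#' @export
extract_barcode <- function(read_sequence, config) {
  stopifnot(length(read_sequence) == 1L)
  extract_barcodes_vec(read_sequence, config)
}

#' Assign an observed barcode to a promoter
#'
#' Substitution-only (Hamming) matching against the map: the unique
#' promoter whose barcode is at minimal distance `<= max_bc_mismatch` wins;
#' ties at the minimal admissible distance are `"ambiguous"` and barcodes
#' with no admissible neighbour are `"unassigned"`. Indels are not
#' modelled: extraction is anchored and barcodes have fixed length.
#'
#' @param observed observed barcode string(s), each of the map's barcode
#'   length.
#' @param map a [barcode_map()].
#' @param max_bc_mismatch maximum admissible Hamming distance.
#' @return Character vector: promoter id, `"unassigned"`, or `"ambiguous"`.
#' @export
match_barcode <- function(observed, map, max_bc_mismatch = 1L) {
  stopifnot(inherits(map, "barcode_map"))
  bcl <- attr(map, "bc_length")
  if (any(nchar(observed) != bcl)) {
    stop("observed barcode length differs from the map's barcode length (",
         bcl, ")")
  }
  match_barcodes_unique(observed, map, max_bc_mismatch)
}

# Vectorized matcher; deduplicates observed barcodes before the Hamming
# scan so cost scales with distinct barcodes, not reads.
match_barcodes_unique <- function(observed, map, max_bc_mismatch) {
  uo <- unique(observed)
  bcm <- char_matrix(map$barcode) # L x n_promoters
  ids <- map$promoter_id
  res_u <- vapply(uo, function(o) {
    oc <- strsplit(o, "", fixed = TRUE)[[1L]]
    d <- colSums(bcm != oc)
    dmin <- min(d)
    if (dmin > max_bc_mismatch) return("unassigned")
    if (sum(d == dmin) > 1L) return("ambiguous")
    ids[[which.min(d)]]
  }, character(1))
  unname(res_u[match(observed, uo)])
}

#' Count barcoded reads of one sample
#'
#' One pass over a FASTQ (plain or gzipped): each read goes through
#' [extract_barcode()] and [match_barcode()]; assigned reads increment
#' their promoter's count and failures are tallied. The bookkeeping is
#' conservative: `sum(counts) + reads_no_anchor + reads_bc_unassigned +
#' reads_bc_ambiguous == reads_seen`, exactly. Phred qualities are parsed
#' by the FASTQ reader but not used for filtering.
#'
#' @param fastq_path path to a FASTQ or FASTQ.gz file.
#' @param map a [barcode_map()].
#' @param config an [amplicon_config()].
#' @param sample_id label stored with the table.
#' @return A `barcode_counts` object: list with `sample_id`, `counts`
#'   (named integer vector over all map promoters), and `qc` tallies.
#' @export
count_sample <- function(fastq_path, map, config, sample_id = basename(fastq_path)) {
  if (!file.exists(fastq_path)) stop("FASTQ not found: ", fastq_path)
  n_lines <- length(readLines(fastq_path, warn = FALSE))
  if (n_lines %% 4L != 0L) {
    stop("truncated FASTQ '", fastq_path, "': record ", n_lines %/% 4L + 1L,
         " is incomplete")
  }
  seqs <- if (n_lines == 0L) character(0) else {
    as.character(Biostrings::readDNAStringSet(fastq_path, format = "fastq"))
  }
  count_sequences(seqs, map, config, sample_id)
}

#' Count barcoded reads held in memory
#'
#' Same semantics as [count_sample()] for a character vector of read
#' sequences.
#'
#' @param seqs character vector of reads.
#' @inheritParams count_sample
#' @return A `barcode_counts` object.
#' @export
count_sequences <- function(seqs, map, config, sample_id = "sample") {
  stopifnot(inherits(map, "barcode_map"), inherits(config, "amplicon_config"))
  if (attr(map, "bc_length") != config$bc_length) {
    stop("map barcode length and config bc_length differ")
  }
  counts <- structure(integer(nrow(map)), names = map$promoter_id)
  n <- length(seqs)
  bc <- extract_barcodes_vec(seqs, config)
  no_anchor <- sum(is.na(bc))
  bc_ok <- bc[!is.na(bc)]
  unassigned <- 0L
  ambiguous <- 0L
  if (length(bc_ok)) {
    assign <- match_barcodes_unique(bc_ok, map, config$max_bc_mismatch)
    unassigned <- sum(assign == "unassigned")
    ambiguous <- sum(assign == "ambiguous")
    hit <- assign[assign != "unassigned" & assign != "ambiguous"]
    if (length(hit)) {
      tab <- table(factor(hit, levels = map$promoter_id))
      counts <- counts + as.integer(tab)
      names(counts) <- map$promoter_id
    }
  }
  structure(list(sample_id = sample_id,
                 counts = counts,
                 qc = list(reads_seen = n,
                           reads_no_anchor = no_anchor,
                           reads_bc_unassigned = unassigned,
                           reads_bc_ambiguous = ambiguous)),
            class = "barcode_counts")
}

#' @export
print.barcode_counts <- function(x, ...) {
  q <- x$qc
  cat(sprintf(
    "Barcode counts '%s': %d reads, %d assigned (%d no-anchor, %d unassigned, %d ambiguous)\n",
    x$sample_id, q$reads_seen, sum(x$counts), q$reads_no_anchor,
    q$reads_bc_unassigned, q$reads_bc_ambiguous))
  invisible(x)
}

#' Write / read a per-sample count table
#'
#' Counts are stored as `promoter_id<TAB>count`; QC tallies are stored as
#' `#key value` header comments so the table round-trips.
#'
#' @param x a `barcode_counts` object.
#' @param path output TSV path.
#' @return `path` (write) or a `barcode_counts` object (read).
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "barcode_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#sample_id %s", x$sample_id),
               sprintf("#%s %d", names(x$qc), unlist(x$qc)),
               "promoter_id\tcount",
               sprintf("%s\t%d", names(x$counts), x$counts)), con)
  invisible(path)
}

#' @rdname write_counts
#' @param path TSV path written by [write_counts()].
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), " ", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
  body <- utils::read.delim(text = lines[!grepl("^#", lines)],
                            stringsAsFactors = FALSE)
  qc_keys <- c("reads_seen", "reads_no_anchor", "reads_bc_unassigned",
               "reads_bc_ambiguous")
  structure(list(sample_id = unname(meta[["sample_id"]]),
                 counts = stats::setNames(as.integer(body$count),
                                          body$promoter_id),
                 qc = as.list(stats::setNames(as.integer(meta[qc_keys]),
                                              qc_keys))),
            class = "barcode_counts")
}
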