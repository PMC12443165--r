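# Barcoded library data model: barcode maps, pooling arithmetic, and
# generation of new barcode sets with a minimum pairwise Hamming distance.

#' Construct and validate a barcode map
#'
#' A barcode map links each promoter construct to the unique DNA barcode
#' carried in the 3' UTR of its reporter cassette. Validation enforces
#' non-empty, unique promoter identifiers, a fixed barcode length, the
#' ACGT alphabet, and pairwise-distinct barcodes. The minimum pairwise
#' Hamming distance of the set is recorded (reported, not enforced: the
#' distance of the original barcode set is unknown).
#'
#' @param x data.frame with columns `promoter_id` and `barcode`; any extra
#'   columns are carried along as opaque metadata.
#' @param bc_length required barcode length in nt (default 15, the library's
#'   barcode size).
#' @return A `barcode_map`: the validated data.frame (barcodes uppercased)
#'   with attribute `min_hamming`.
#' @seealso [load_barcode_map()], [generate_barcodes()]
#' @examples
#' barcode_map(data.frame(promoter_id = c("P1", "P2"),
#'                        barcode = c("ACGTACGTACGTACG", "TTTTTTTTTTTTTTT")))
#' @export
barcode_map <- function(x, bc_length = 15L) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(c("promoter_id", "barcode"), names(x))
  if (length(missing_cols)) {
    stop("barcode map lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x$promoter_id <- as.character(x$promoter_id)
  x$barcode <- toupper(as.character(x$barcode))

  if (any(!nzchar(x$promoter_id)) || anyNA(x$promoter_id)) {
    stop("promoter_id must be non-empty for every entry")
  }
  dup_id <- x$promoter_id[duplicated(x$promoter_id)]
  if (length(dup_id)) {
    stop("duplicate promoter_id: ", paste(unique(dup_id), collapse = ", "))
  }

  bad_len <- which(nchar(x$barcode) != bc_length)
  if (length(bad_len)) {
    i <- bad_len[[1L]]
    stop("barcode of promoter '", x$promoter_id[[i]], "' (line ", i + 1L,
         ") has length ", nchar(x$barcode[[i]]), " != ", bc_length)
  }
  bad_alpha <- grepl("[^ACGT]", x$barcode)
  if (any(bad_alpha)) {
    i <- which(bad_alpha)[[1L]]
    stop("barcode of promoter '", x$promoter_id[[i]], "' (line ", i + 1L,
         ") contains characters outside ACGT")
  }

  dup_bc <- unique(x$barcode[duplicated(x$barcode)])
  if (length(dup_bc)) {
    offenders <- x$promoter_id[x$barcode %in% dup_bc]
    stop("duplicate barcode(s) shared by promoters: ",
         paste(offenders, collapse = ", "))
  }

  attr(x, "bc_length") <- as.integer(bc_length)
  attr(x, "min_hamming") <- min_pairwise_hamming(x$barcode)
  class(x) <- c("barcode_map", "data.frame")
  x
}

#' Load a barcode map from a TSV file
#'
#' Expects a tab-separated file with a header containing at least
#' `promoter_id` and `barcode`; additional columns are preserved as
#' metadata. Error messages reference the offending file line (header is
#' line 1).
#'
#' @param path path to the TSV file.
#' @inheritParams barcode_map
#' @return A validated [barcode_map()].
#' @export
load_barcode_map <- function(path, bc_length = 15L) {
  if (!file.exists(path)) stop("barcode map file not found: ", path)
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  barcode_map(x, bc_length = bc_length)
}

#' Write a barcode map to a TSV file
#'
#' Inverse of [load_barcode_map()]; loading the written file round-trips to
#' an identical map.
#'
#' @param map a [barcode_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_barcode_map <- function(map, path) {
  stopifnot(inherits(map, "barcode_map"))
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' @param barcodes character vector of equal-length sequences.
#' @return Integer minimum distance over all pairs, or `NA` for fewer than
#'   two barcodes.
#' @export
min_pairwise_hamming <- function(barcodes) {
  n <- length(barcodes)
  if (n < 2L) return(NA_integer_)
  m <- char_matrix(barcodes)
  best <- nrow(m)
  for (i in seq_len(n - 1L)) {
    d <- colSums(m[, (i + 1L):n, drop = FALSE] != m[, i])
    best <- min(best, d)
    if (best == 0L) break
  }
  as.integer(best)
}

#' Pooling arithmetic for an equimolar vector library
#'
#' Equal vector-genome (VG) amounts of each barcoded construct are pooled,
#' so the total dose is the per-construct dose times the number of
#' constructs. For the 53-promoter library dosed at 1e11 VG per construct
#' per mouse this gives a 5.3e12 VG/mouse total.
#'
#' @param n_constructs number of constructs in the pool (> 0).
#' @param dose_per_construct VGs of each construct per animal (> 0).
#' @return A `pool_plan` list with `n_constructs`, `dose_per_construct`,
#'   and `total_dose`.
#' @examples
#' pool_dose(53, 1e11)$total_dose # 5.3e12
#' @export
pool_dose <- function(n_constructs, dose_per_construct) {
  if (!is.numeric(n_constructs) || length(n_constructs) != 1L ||
      !is.finite(n_constructs) || n_constructs <= 0) {
    stop("n_constructs must be a positive number")
  }
  if (!is.numeric(dose_per_construct) || length(dose_per_construct) != 1L ||
      !is.finite(dose_per_construct) || dose_per_construct <= 0) {
    stop("dose_per_construct must be a positive number")
  }
  structure(list(n_constructs = n_constructs,
                 dose_per_construct = dose_per_construct,
                 total_dose = n_constructs * dose_per_construct),
            class = "pool_plan")
}

#' @export
print.pool_plan <- function(x, ...) {
  cat(sprintf("Pool plan: %g constructs x %g VG = %g VG total\n",
              x$n_constructs, x$dose_per_construct, x$total_dose))
  invisible(x)
}

#' Generate a barcode set with a minimum pairwise Hamming distance
#'
#' Seeded rejection sampling: random ACGT sequences are drawn and kept only
#' if at least `min_hamming` substitutions away from every barcode accepted
#' so far. Deterministic for a fixed seed. Adequate for library-scale sets
#' (tens to a few hundred barcodes); infeasible constraints abort with an
#' error after `max_attempts` draws.
#'
#' @param n number of barcodes (>= 1).
#' @param length barcode length in nt.
#' @param min_hamming required minimum pairwise distance (>= 1).
#' @param seed integer RNG seed.
#' @param max_attempts rejection-sampling draw cap (default 1e6).
#' @return Character vector of `n` distinct barcodes.
#' @examples
#' generate_barcodes(4, 8, min_hamming = 3, seed = 1)
#' @export
generate_barcodes <- function(n, length, min_hamming = 1L, seed = 1L,
                              max_attempts = 1e6) {
  stopifnot(is_count(n), is_count(length), is_count(min_hamming))
  if (min_hamming > length) stop("min_hamming cannot exceed barcode length")
  if (log(n) > length * log(4)) {
    stop("infeasible: only 4^", length, " sequences of length ", length,
         " exist; requested ", n,
         ". Use a longer barcode or a smaller set.")
  }
  alphabet <- c("A", "C", "G", "T")
  with_seed(seed, {
    kept <- character(0)
    kept_m <- matrix(character(), nrow = length, ncol = 0L)
    attempts <- 0L
    while (base::length(kept) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("could not place ", n, " barcodes of length ", length,
             " at pairwise Hamming distance >= ", min_hamming, " within ",
             format(max_attempts, scientific = FALSE),
             " draws. Use a longer barcode or a smaller set.")
      }
      cand <- sample(alphabet, length, replace = TRUE)
      if (ncol(kept_m) == 0L ||
          min(colSums(kept_m != cand)) >= min_hamming) {
        kept <- c(kept, paste(cand, collapse = ""))
        kept_m <- cbind(kept_m, cand)
      }
    }
    kept
  })
}
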