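# Library-screen normalization cascade: barcode proportions, normalized
# expression R = (P_cDNA / P_gDNA) x C_bulk, and its deconstruction into
# efficiency scores (rescaled across promoters within a tissue) and
# specificity scores (rescaled across tissues within a promoter).

#' Validate a sample sheet
#'
#' @param x data.frame with columns `sample_id`, `animal_id`, `tissue`,
#'   `material` (one of `gDNA`, `cDNA`, `library_stock`).
#' @return The validated data.frame with class `sample_sheet`.
#' @export
sample_sheet <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("sample_id", "animal_id", "tissue", "material")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  x[need] <- lapply(x[need], as.character)
  bad <- setdiff(unique(x$material), c("gDNA", "cDNA", "library_stock"))
  if (length(bad)) stop("unknown material: ", paste(bad, collapse = ", "))
  key <- paste(x$animal_id, x$tissue, x$material, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (animal, tissue, material) combination in sample sheet")
  }
  cdna <- x[x$material == "cDNA", ]
  gkey <- paste(x$animal_id, x$tissue)[x$material == "gDNA"]
  orphan <- !(paste(cdna$animal_id, cdna$tissue) %in% gkey)
  if (any(orphan)) {
    stop("cDNA sample(s) without a matching gDNA sample: ",
         paste(sprintf("(%s, %s)", cdna$animal_id[orphan],
                       cdna$tissue[orphan]), collapse = ", "))
  }
  class(x) <- c("sample_sheet", "data.frame")
  x
}

#' Barcode proportions of one sample
#'
#' Each promoter's assigned read count divided by the sample's total
#' assigned reads. Ambiguous and unassigned reads are excluded: they carry
#' no promoter identity and would add promoter-independent noise. Samples
#' below the read-depth threshold are flagged failed (returned as `NULL`
#' with a warning) rather than propagated.
#'
#' @param counts a `barcode_counts` object or a named numeric vector.
#' @param min_reads minimum total assigned reads for a usable sample
#'   (default 1000).
#' @return Named numeric vector of proportions summing to 1, or `NULL`
#'   for a failed sample.
#' @export
proportions <- function(counts, min_reads = 1000) {
  v <- if (inherits(counts, "barcode_counts")) counts$counts else counts
  stopifnot(is.numeric(v), !is.null(names(v)))
  total <- sum(v)
  if (total < min_reads) {
    id <- if (inherits(counts, "barcode_counts")) counts$sample_id else "sample"
    warning("sample '", id, "' has ", total, " assigned reads (< ",
            min_reads, "); flagged failed and excluded")
    return(NULL)
  }
  v / total
}

#' Normalized expression from paired proportion matrices
#'
#' Computes `R = (P_cDNA / P_gDNA) * C_bulk` element-wise over a promoters
#' x samples grid, where each column is one (animal, tissue) pair and
#' `C_bulk` is that pair's bulk reporter expression (2^-deltaCt against a
#' housekeeper). Entries whose gDNA signal sits below the detection floor
#' are masked (`NA`), never infinite: a near-zero delivery denominator
#' makes the ratio explosive, so such cells are treated as unmeasured.
#'
#' @param p_cdna,p_gdna numeric matrices (promoters x samples) with
#'   identical dimnames; columns are (animal, tissue) pairs.
#' @param c_bulk numeric vector of bulk expression values, one per column.
#' @param animals,tissues optional character vectors labelling the columns.
#' @param mask optional logical matrix of entries to mask in addition to
#'   zero-gDNA cells (e.g. a count-based detection floor).
#' @return A `normalized_expression` object: list with matrix `R` (masked
#'   entries `NA`), logical `mask`, and `colData` (animal, tissue per
#'   column).
#' @export
normalized_expression <- function(p_cdna, p_gdna, c_bulk,
                                  animals = NULL, tissues = NULL,
                                  mask = NULL) {
  p_cdna <- as.matrix(p_cdna)
  p_gdna <- as.matrix(p_gdna)
  if (!identical(dim(p_cdna), dim(p_gdna))) {
    stop("cDNA and gDNA proportion matrices differ in shape")
  }
  if (length(c_bulk) == 1L) c_bulk <- rep(c_bulk, ncol(p_cdna))
  stopifnot(length(c_bulk) == ncol(p_cdna), all(c_bulk > 0, na.rm = TRUE))
  m <- (p_gdna <= 0) | !is.finite(p_gdna) | !is.finite(p_cdna)
  if (!is.null(mask)) m <- m | mask
  R <- sweep(p_cdna / p_gdna, 2L, c_bulk, `*`)
  R[m] <- NA_real_
  colData <- data.frame(
    animal = animals %||% rep(NA_character_, ncol(R)),
    tissue = tissues %||% colnames(R) %||% paste0("s", seq_len(ncol(R))),
    stringsAsFactors = FALSE)
  structure(list(R = R, mask = m, colData = colData),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf(
    "Normalized expression: %d promoters x %d (animal, tissue) samples; %d masked entries\n",
    nrow(x$R), ncol(x$R), sum(x$mask)))
  invisible(x)
}

new_score_matrix <- function(values, axis, colData = NULL,
                             mean = NULL, sd = NULL, n = NULL) {
  structure(list(values = values, axis = axis, colData = colData,
                 mean = mean, sd = sd, n = n),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  axis_lab <- paste0(toupper(substring(x$axis, 1L, 1L)), substring(x$axis, 2L))
  cat(sprintf("%s scores: %d promoters x %d columns%s\n",
              axis_lab, nrow(x$values), ncol(x$values),
              if (!is.null(x$mean)) " (aggregated: mean/sd/n)" else ""))
  invisible(x)
}

#' Efficiency scores: which promoter is strongest within a tissue
#'
#' For each (animal, tissue) column, every promoter's normalized expression
#' is divided by the column sum over all promoters and scaled by 100, so
#' scores within a tissue sum to 100. The bulk expression factor of a
#' tissue cancels within the column, so efficiency is invariant to it.
#'
#' @param ne a [normalized_expression()] object.
#' @return A `score_matrix` with per-column scores in `[0, 100]`.
#' @export
efficiency_scores <- function(ne) {
  stopifnot(inherits(ne, "normalized_expression"))
  R <- ne$R
  tot <- colSums(R, na.rm = TRUE)
  dead <- colSums(!is.na(R)) == 0L
  if (any(dead)) {
    warning("tissue column(s) with all entries masked dropped: ",
            paste(colnames(R)[dead] %||% which(dead), collapse = ", "))
    R <- R[, !dead, drop = FALSE]
    tot <- tot[!dead]
    ne$colData <- ne$colData[!dead, , drop = FALSE]
  }
  E <- 100 * sweep(R, 2L, tot, `/`)
  new_score_matrix(E, axis = "efficiency", colData = ne$colData)
}

#' Specificity scores: where a promoter acts
#'
#' For each promoter, within each animal, normalized expression is divided
#' by the promoter's sum over that animal's tissues and scaled by 100, so
#' scores across tissues sum to 100 per promoter per animal. Because the
#' within-animal tissue sum is the denominator, scaling the bulk expression
#' of one tissue shifts specificity towards that tissue.
#'
#' @param ne a [normalized_expression()] object whose `colData` carries
#'   animal and tissue labels.
#' @return A `score_matrix`, same shape as the input matrix.
#' @export
specificity_scores <- function(ne) {
  stopifnot(inherits(ne, "normalized_expression"))
  R <- ne$R
  S <- R
  for (a in unique(ne$colData$animal)) {
    cols <- which(ne$colData$animal == a)
    tot <- rowSums(R[, cols, drop = FALSE], na.rm = TRUE)
    S[, cols] <- 100 * R[, cols, drop = FALSE] / tot
  }
  dead <- rowSums(!is.na(S)) == 0L
  if (any(dead)) {
    warning("promoter(s) with all entries masked dropped: ",
            paste(rownames(R)[dead] %||% which(dead), collapse = ", "))
    S <- S[!dead, , drop = FALSE]
  }
  new_score_matrix(S, axis = "specificity", colData = ne$colData)
}

#' Aggregate per-animal scores into replicate statistics
#'
#' Element-wise mean and sample standard deviation across animals for each
#' (promoter, tissue) cell, masked cells excluded; the number of animals
#' contributing to each cell is recorded. Accepts either one combined
#' per-animal `score_matrix` (columns labelled with animal and tissue) or a
#' list of per-animal `score_matrix` objects sharing the same promoter and
#' tissue index.
#'
#' @param scores a `score_matrix` or a list of them.
#' @return A `score_matrix` whose `values` are the mean promoters x tissues
#'   matrix, with `sd` and `n` matrices alongside.
#' @export
aggregate_replicates <- function(scores) {
  if (is.list(scores) && !inherits(scores, "score_matrix")) {
    stopifnot(length(scores) >= 1L,
              all(vapply(scores, inherits, TRUE, "score_matrix")))
    ref <- scores[[1L]]
    for (s in scores[-1L]) {
      if (!identical(rownames(s$values), rownames(ref$values)) ||
          !identical(s$colData$tissue, ref$colData$tissue)) {
        stop("promoter x tissue index mismatch across animals")
      }
    }
    values <- do.call(cbind, lapply(scores, `[[`, "values"))
    colData <- do.call(rbind, lapply(scores, `[[`, "colData"))
    scores <- new_score_matrix(values, ref$axis, colData)
  }
  stopifnot(inherits(scores, "score_matrix"))
  tissues <- unique(scores$colData$tissue)
  V <- scores$values
  dn <- list(rownames(V), tissues)
  agg <- function(f) {
    out <- vapply(tissues, function(tb) {
      cols <- which(scores$colData$tissue == tb)
      apply(V[, cols, drop = FALSE], 1L, f)
    }, numeric(nrow(V)))
    matrix(out, nrow = nrow(V), dimnames = dn)
  }
  m <- agg(function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  s <- agg(function(v) if (sum(!is.na(v)) < 2L) NA_real_ else
    stats::sd(v, na.rm = TRUE))
  n <- agg(function(v) sum(!is.na(v)))
  new_score_matrix(m, scores$axis,
                   colData = data.frame(tissue = tissues,
                                        stringsAsFactors = FALSE),
                   mean = m, sd = s, n = n)
}

#' Run the full screen normalization cascade
#'
#' From per-sample barcode count tables, a sample sheet, and bulk reporter
#' expression values to normalized expression and per-animal scores:
#' proportions are computed over assigned reads, cDNA and gDNA samples are
#' paired per (animal, tissue), `R = (P_cDNA / P_gDNA) * C_bulk` is formed,
#' and promoters with fewer than `gdna_floor` assigned gDNA reads in a
#' sample are masked for that sample (the ratio denominator is explosive at
#' low counts). No pseudocounts are added anywhere; masking is the sole
#' zero-handling mechanism, because pseudocounts silently bias ratios of
#' proportions.
#'
#' @param counts named list of `barcode_counts`, names matching
#'   `sample_id` in the sheet.
#' @param samples a [sample_sheet()] (or data.frame coercible to one).
#' @param bulk data.frame with columns `animal_id`, `tissue`, `c_beta`
#'   (bulk 2^-deltaCt reporter expression). If `animal_id` is absent the
#'   per-tissue values are broadcast to all animals (with a notice).
#' @param min_reads per-sample assigned-read threshold (see
#'   [proportions()]).
#' @param gdna_floor gDNA read-count detection floor per promoter per
#'   sample (default 10).
#' @return A list with `ne` ([normalized_expression()]), per-animal
#'   `efficiency` and `specificity` score matrices, and their
#'   [aggregate_replicates()] summaries `efficiency_mean`,
#'   `specificity_mean`.
#' @export
quantify_screen <- function(counts, samples, bulk, min_reads = 1000,
                            gdna_floor = 10) {
  samples <- sample_sheet(as.data.frame(samples))
  stopifnot(is.list(counts))
  if (is.null(names(counts))) {
    names(counts) <- vapply(counts, `[[`, "", "sample_id")
  }
  if (!("animal_id" %in% names(bulk))) {
    message("bulk expression supplied per tissue only; ",
            "broadcasting to all animals")
    animals <- unique(samples$animal_id[samples$material != "library_stock"])
    bulk <- do.call(rbind, lapply(animals, function(a) {
      data.frame(animal_id = a, tissue = bulk$tissue, c_beta = bulk$c_beta,
                 stringsAsFactors = FALSE)
    }))
  }

  pairs <- unique(samples[samples$material == "cDNA",
                          c("animal_id", "tissue")])
  sid <- function(a, tb, mat) {
    samples$sample_id[samples$animal_id == a & samples$tissue == tb &
                        samples$material == mat]
  }

  promoters <- names(counts[[1L]]$counts)
  keep <- list()
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$animal_id[[k]]; tb <- pairs$tissue[[k]]
    gid <- sid(a, tb, "gDNA"); cid <- sid(a, tb, "cDNA")
    if (length(gid) != 1L || length(cid) != 1L ||
        !(gid %in% names(counts)) || !(cid %in% names(counts))) {
      stop("unpaired sample for (", a, ", ", tb, ")")
    }
    cb <- bulk$c_beta[bulk$animal_id == a & bulk$tissue == tb]
    if (length(cb) != 1L || is.na(cb)) {
      stop("missing bulk expression C for (", a, ", ", tb, ")")
    }
    pg <- proportions(counts[[gid]], min_reads)
    pc <- proportions(counts[[cid]], min_reads)
    if (is.null(pg) || is.null(pc)) next
    keep[[length(keep) + 1L]] <- list(
      animal = a, tissue = tb, pg = pg[promoters], pc = pc[promoters],
      gcounts = counts[[gid]]$counts[promoters], c_beta = cb)
  }
  if (!length(keep)) stop("no usable (animal, tissue) pairs after filtering")

  p_g <- vapply(keep, `[[`, numeric(length(promoters)), "pg")
  p_c <- vapply(keep, `[[`, numeric(length(promoters)), "pc")
  gc <- vapply(keep, `[[`, numeric(length(promoters)), "gcounts")
  rownames(p_g) <- rownames(p_c) <- rownames(gc) <- promoters
  animals <- vapply(keep, `[[`, "", "animal")
  tissues <- vapply(keep, `[[`, "", "tissue")
  colnames(p_g) <- colnames(p_c) <- paste(animals, tissues, sep = "|")
  cb <- vapply(keep, `[[`, 0, "c_beta")

  ne <- normalized_expression(p_c, p_g, cb, animals = animals,
                              tissues = tissues, mask = gc < gdna_floor)
  E <- efficiency_scores(ne)
  S <- specificity_scores(ne)
  list(ne = ne,
       efficiency = E, specificity = S,
       efficiency_mean = aggregate_replicates(E),
       specificity_mean = aggregate_replicates(S))
}
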