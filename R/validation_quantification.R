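# Single-vector validation arithmetic: delta-Ct relative expression from
# qPCR, vector genomes per diploid genome from ddPCR, their ratio Q, and
# the validation-screen efficiency/specificity scores.

#' Relative expression from qPCR Ct duplicates (2^-deltaCt)
#'
#' Technical duplicates are averaged on the Ct (log) scale, as in standard
#' delta-Ct practice, then `C = 2^-(mean Ct_target - mean Ct_housekeeper)`.
#' Duplicates whose spread exceeds the concordance window are flagged but
#' still computed; undetermined Ct values (no amplification) are passed as
#' `NA` and treated as missing, never imputed to a cycle ceiling, because a
#' ceiling fabricates an expression value.
#'
#' @param ct_target numeric vector of target (reporter) Ct replicates.
#' @param ct_housekeeper numeric vector of housekeeper Ct replicates.
#' @param window duplicate concordance window in cycles (default 1).
#' @return List with `expression` (2^-deltaCt, `NA` if either side has no
#'   valid replicate), `delta_ct`, and logical `flagged`.
#' @examples
#' relative_expression(c(20, 21), c(24, 24))$expression # 2^3.5
#' @export
relative_expression <- function(ct_target, ct_housekeeper, window = 1) {
  check_ct <- function(x, what) {
    if (any(x <= 0, na.rm = TRUE)) stop(what, " Ct values must be positive")
    x[!is.na(x)]
  }
  t_ok <- check_ct(ct_target, "target")
  h_ok <- check_ct(ct_housekeeper, "housekeeper")
  if (!length(t_ok) || !length(h_ok)) {
    return(list(expression = NA_real_, delta_ct = NA_real_, flagged = FALSE))
  }
  spread <- function(x) if (length(x) < 2L) 0 else diff(range(x))
  flagged <- spread(t_ok) > window || spread(h_ok) > window
  delta <- mean(t_ok) - mean(h_ok)
  list(expression = 2^(-delta), delta_ct = delta, flagged = flagged)
}

#' Vector genomes per diploid genome from ddPCR copy counts
#'
#' The autosomal reference Rpp30 is present at two copies per diploid
#' genome, so its copy count divided by two gives diploid genomes and
#' `G = reporter copies / (Rpp30 / 2)`. The ratio of the two channels is
#' independent of input mass, so differing DNA inputs between tissues need
#' no correction.
#'
#' @param eyfp_copies reporter (vector) copy counts, `>= 0`.
#' @param rpp30_copies reference-gene copy counts; zero yields a masked
#'   (`NA`) sample with a warning.
#' @return Numeric vector of VG per diploid genome.
#' @examples
#' vg_per_diploid_genome(1000, 2000) # 1
#' @export
vg_per_diploid_genome <- function(eyfp_copies, rpp30_copies) {
  if (any(eyfp_copies < 0, na.rm = TRUE) ||
      any(rpp30_copies < 0, na.rm = TRUE)) {
    stop("copy counts must be non-negative")
  }
  zero <- !is.na(rpp30_copies) & rpp30_copies == 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero Rpp30 copies masked")
  }
  g <- eyfp_copies / (rpp30_copies / 2)
  g[zero] <- NA_real_
  g
}

#' Normalized single-vector expression Q = C / G
#'
#' Expression per delivered vector copy: relative expression divided by
#' vector genomes per diploid genome. Cells without measurable delivery
#' (`G` zero or missing) are masked.
#'
#' @param c_rel relative expression values (2^-deltaCt).
#' @param g vector genomes per diploid genome.
#' @return Numeric vector `Q`, `NA` where masked.
#' @export
normalized_single <- function(c_rel, g) {
  bad <- is.na(g) | g == 0
  if (any(bad & !is.na(c_rel))) {
    message(sum(bad & !is.na(c_rel)),
            " cell(s) masked: no measurable vector delivery")
  }
  q <- c_rel / g
  q[bad] <- NA_real_
  q
}

#' Combine qPCR and ddPCR tables into per-cell C, G, Q
#'
#' Merges the two measurement tables on (animal, tissue, promoter) and
#' applies [relative_expression()], [vg_per_diploid_genome()], and
#' [normalized_single()] row-wise.
#'
#' @param qpcr data.frame with columns `animal`, `tissue`, `promoter`,
#'   `ct_target_rep1`, `ct_target_rep2`, `ct_hk_rep1`, `ct_hk_rep2`.
#' @param ddpcr data.frame with columns `animal`, `tissue`, `promoter`,
#'   `eyfp_copies`, `rpp30_copies`.
#' @param window duplicate concordance window in cycles.
#' @return data.frame with columns `animal`, `tissue`, `promoter`, `c`,
#'   `g`, `q`, `flagged`.
#' @export
single_vector_expression <- function(qpcr, ddpcr, window = 1) {
  need_q <- c("animal", "tissue", "promoter", "ct_target_rep1",
              "ct_target_rep2", "ct_hk_rep1", "ct_hk_rep2")
  need_d <- c("animal", "tissue", "promoter", "eyfp_copies", "rpp30_copies")
  stopifnot(all(need_q %in% names(qpcr)), all(need_d %in% names(ddpcr)))
  # order-preserving join on (animal, tissue, promoter): qPCR row order
  # (and hence tissue/promoter ordering downstream) is kept as supplied
  key <- function(d) paste(d$animal, d$tissue, d$promoter, sep = "\r")
  idx <- match(key(qpcr), key(ddpcr))
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[[1L]]
    stop("no ddPCR measurement for (", qpcr$animal[[miss]], ", ",
         qpcr$tissue[[miss]], ", ", qpcr$promoter[[miss]], ")")
  }
  x <- cbind(qpcr, ddpcr[idx, c("eyfp_copies", "rpp30_copies"),
                         drop = FALSE])
  rownames(x) <- NULL
  rel <- lapply(seq_len(nrow(x)), function(i) {
    relative_expression(c(x$ct_target_rep1[[i]], x$ct_target_rep2[[i]]),
                        c(x$ct_hk_rep1[[i]], x$ct_hk_rep2[[i]]),
                        window = window)
  })
  x$c <- vapply(rel, `[[`, 0, "expression")
  x$flagged <- vapply(rel, `[[`, TRUE, "flagged")
  x$g <- vg_per_diploid_genome(x$eyfp_copies, x$rpp30_copies)
  x$q <- normalized_single(x$c, x$g)
  # promoters with no expression (C == NA from missing Ct) stay NA in q
  x[, c("animal", "tissue", "promoter", "c", "g", "q", "flagged")]
}

#' Efficiency and specificity scores for a single-vector cohort
#'
#' Mirrors the screen-score arithmetic on normalized expression `Q`:
#' specificity is computed per animal (each animal carries one promoter,
#' so `S = 100 * Q / sum over tissues`), while efficiency is computed per
#' tissue from `Q*`, the mean of `Q` across each promoter's replicate
#' animals (`E = 100 * Q* / sum over promoters`).
#'
#' @param sv data.frame from [single_vector_expression()] (columns
#'   `animal`, `tissue`, `promoter`, `q`).
#' @return List with `efficiency` (a `score_matrix`, promoters x tissues)
#'   and `specificity` (a `score_matrix` of per-animal scores with
#'   aggregated mean/sd/n across animals).
#' @export
validation_scores <- function(sv) {
  stopifnot(all(c("animal", "tissue", "promoter", "q") %in% names(sv)))
  promoters <- unique(sv$promoter)
  tissues <- unique(sv$tissue)

  # mean Q* across replicate animals, per (promoter, tissue)
  qstar <- vapply(tissues, function(tb) {
    vapply(promoters, function(p) {
      v <- sv$q[sv$promoter == p & sv$tissue == tb]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, 0)
  }, numeric(length(promoters)))
  dimnames(qstar) <- list(promoters, tissues)
  miss <- colSums(is.na(qstar)) > 0L
  if (any(miss)) {
    warning("tissue(s) with a promoter missing Q masked in efficiency: ",
            paste(tissues[miss], collapse = ", "))
  }
  E <- 100 * sweep(qstar, 2L, colSums(qstar, na.rm = TRUE), `/`)

  # per-animal specificity across tissues
  animals <- unique(sv[, c("animal", "promoter")])
  Sv <- vapply(seq_len(nrow(animals)), function(k) {
    v <- vapply(tissues, function(tb) {
      q <- sv$q[sv$animal == animals$animal[[k]] & sv$tissue == tb]
      if (length(q) != 1L) NA_real_ else q
    }, 0)
    100 * v / sum(v, na.rm = TRUE)
  }, numeric(length(tissues)))
  # orient as rows = (promoter, animal), columns = tissues
  Sv <- t(Sv)
  rownames(Sv) <- paste(animals$promoter, animals$animal, sep = "|")
  colnames(Sv) <- tissues

  s_mean <- vapply(tissues, function(tb) {
    vapply(promoters, function(p) {
      v <- Sv[animals$promoter == p, tb]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, 0)
  }, numeric(length(promoters)))
  s_sd <- vapply(tissues, function(tb) {
    vapply(promoters, function(p) {
      v <- Sv[animals$promoter == p, tb]
      if (sum(!is.na(v)) < 2L) NA_real_ else stats::sd(v, na.rm = TRUE)
    }, 0)
  }, numeric(length(promoters)))
  s_n <- vapply(tissues, function(tb) {
    vapply(promoters, function(p) sum(!is.na(Sv[animals$promoter == p, tb])), 0)
  }, numeric(length(promoters)))
  dimnames(s_mean) <- dimnames(s_sd) <- dimnames(s_n) <-
    list(promoters, tissues)

  list(
    efficiency = new_score_matrix(
      E, axis = "efficiency",
      colData = data.frame(tissue = tissues, stringsAsFactors = FALSE)),
    specificity = new_score_matrix(
      Sv, axis = "specificity",
      colData = data.frame(animal = animals$animal,
                           promoter = animals$promoter,
                           stringsAsFactors = FALSE),
      mean = s_mean, sd = s_sd, n = s_n))
}
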