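# Synthetic promoter screens with known ground truth. The generator
# emulates the study conditions: an equimolar 53-construct pool delivered
# to 6 animals, barcode readout from gDNA and cDNA in 16 tissues,
# multinomial read sampling with per-base substitution error on the FASTQ
# path, and noisy Ct / ddPCR readouts for the single-vector cohort.

default_tissues <- c("brain", "diaphragm", "eye", "fat", "gut", "heart",
                     "kidney", "liver", "lung", "lymph_node", "muscle",
                     "ovary", "pancreas", "skin", "spleen", "stomach")

# Plausible mean vector copies per diploid genome after systemic AAV9
# delivery (synthetic values: strong liver accumulation, moderate heart,
# low CNS). Used as the biodistribution default.
default_biodistribution <- c(
  brain = 0.1, diaphragm = 1, eye = 0.1, fat = 0.5, gut = 0.5, heart = 3,
  kidney = 1.5, liver = 20, lung = 0.8, lymph_node = 0.5, muscle = 1,
  ovary = 0.3, pancreas = 0.8, skin = 0.3, spleen = 1.2, stomach = 0.4)

# True per-copy transcriptional activity matrix. Structure: lognormal
# promoter baselines modulated per tissue, one ubiquitous-strong promoter
# (a CAG-like benchmark), and ~40% of the rest strongly tissue-specific
# (boosted 25x in one tissue, assigned round-robin so each tissue has a
# clear top candidate).
simulate_activity <- function(n_promoters, tissues, seed) {
  nt <- length(tissues)
  with_seed(seed, {
    b <- stats::rlnorm(n_promoters, meanlog = 0, sdlog = 1)
    m <- matrix(stats::rlnorm(n_promoters * nt, meanlog = 0, sdlog = 0.5),
                nrow = n_promoters)
    A <- b * m
    A[1L, ] <- A[1L, ] * 8 # ubiquitous-strong benchmark
    n_spec <- max(0L, round(0.4 * (n_promoters - 1L)))
    if (n_spec > 0L) {
      spec <- sample(2:n_promoters, n_spec)
      target <- rep_len(seq_len(nt), n_spec)
      for (k in seq_len(n_spec)) {
        A[spec[[k]], target[[k]]] <- A[spec[[k]], target[[k]]] * 25
      }
    }
    dimnames(A) <- list(sprintf("P%02d", seq_len(n_promoters)), tissues)
    A
  })
}

#' Ground truth for a synthetic promoter screen
#'
#' Bundles everything the simulator needs: the true activity matrix, the
#' per-tissue biodistribution, pool proportions (uniform by default, as
#' for an equimolar pool), cohort size, sequencing depths, and noise
#' levels. The companion barcode map and amplicon configuration (with
#' synthetic default anchors) are generated alongside so the FASTQ path is
#' concrete. Everything is deterministic for a fixed seed.
#'
#' @param n_promoters number of barcoded constructs (default 53).
#' @param tissues tissue names (default: the 16-tissue panel of a
#'   systemic screen).
#' @param n_animals animals in the library cohort (default 6).
#' @param activity optional promoters x tissues matrix of true per-copy
#'   activities `>= 0`; generated if `NULL`.
#' @param biodistribution optional named per-tissue mean vector copies per
#'   diploid genome, `> 0`.
#' @param pool_proportions optional per-promoter pool proportions summing
#'   to 1 (default uniform).
#' @param depth_gdna,depth_cdna reads per gDNA / cDNA sample (default 1e5).
#' @param base_error per-base substitution probability on the FASTQ path
#'   (default 0.005; must be `< 0.25`).
#' @param ct_sd qPCR Ct noise SD in cycles (default 0.25).
#' @param lognormal_sd SD (log scale) of copy-number and bulk-expression
#'   noise (default 0.2).
#' @param dirichlet_concentration concentration of the per-animal pool
#'   perturbation, `alpha = concentration * L` (default 5000): injection /
#'   biodistribution jitter that gives realistic inter-animal variance
#'   without overwhelming signal.
#' @param c0 bulk-expression scale constant (default 1).
#' @param bc_min_hamming minimum pairwise distance of the generated
#'   barcode set (default 5, comfortably above the 1-mismatch matching
#'   default).
#' @param read_length simulated read length (default 84 nt).
#' @param seed integer seed; every random choice derives from it.
#' @return A `screen_truth` list; notable elements: `activity`,
#'   `biodistribution`, `pool_proportions`, `map` (a [barcode_map()]),
#'   `config` (an [amplicon_config()]).
#' @export
screen_truth <- function(n_promoters = 53L, tissues = default_tissues,
                         n_animals = 6L, activity = NULL,
                         biodistribution = NULL, pool_proportions = NULL,
                         depth_gdna = 1e5, depth_cdna = 1e5,
                         base_error = 0.005, ct_sd = 0.25,
                         lognormal_sd = 0.2, dirichlet_concentration = 5000,
                         c0 = 1, bc_min_hamming = 5L, read_length = 84L,
                         seed = 1L) {
  stopifnot(is_count(n_promoters), is_count(n_animals),
            depth_gdna >= 0, depth_cdna >= 0,
            base_error >= 0, base_error < 0.25, ct_sd >= 0,
            lognormal_sd >= 0, c0 > 0)
  promoters <- sprintf("P%02d", seq_len(n_promoters))
  if (is.null(activity)) {
    activity <- simulate_activity(n_promoters, tissues, seed)
  }
  stopifnot(identical(dim(activity),
                      as.integer(c(n_promoters, length(tissues)))),
            all(activity >= 0))
  dimnames(activity) <- list(promoters, tissues)
  if (is.null(biodistribution)) {
    biodistribution <- default_biodistribution[tissues]
    biodistribution[is.na(biodistribution)] <- 1
    names(biodistribution) <- tissues
  }
  stopifnot(length(biodistribution) == length(tissues),
            all(biodistribution > 0))
  if (is.null(pool_proportions)) {
    pool_proportions <- rep(1 / n_promoters, n_promoters)
  }
  stopifnot(length(pool_proportions) == n_promoters,
            abs(sum(pool_proportions) - 1) < 1e-8)
  names(pool_proportions) <- promoters

  barcodes <- generate_barcodes(n_promoters, length = 15L,
                                min_hamming = bc_min_hamming,
                                seed = seed)
  map <- barcode_map(data.frame(promoter_id = promoters, barcode = barcodes,
                                stringsAsFactors = FALSE))
  config <- amplicon_config(anchor5 = "ATCGGAAGAGCACACGTCTG",
                            anchor3 = "AGATCGGAAG")
  structure(list(activity = activity,
                 biodistribution = biodistribution,
                 pool_proportions = pool_proportions,
                 n_animals = as.integer(n_animals),
                 depth_gdna = depth_gdna, depth_cdna = depth_cdna,
                 base_error = base_error, ct_sd = ct_sd,
                 lognormal_sd = lognormal_sd,
                 dirichlet_concentration = dirichlet_concentration,
                 c0 = c0, read_length = as.integer(read_length),
                 map = map, config = config, seed = as.integer(seed)),
            class = "screen_truth")
}

#' @export
print.screen_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic screen truth: %d promoters x %d tissues, %d animals, depth %g/%g, base error %g, seed %d\n",
    nrow(x$activity), ncol(x$activity), x$n_animals,
    x$depth_gdna, x$depth_cdna, x$base_error, x$seed))
  invisible(x)
}

#' True within-tissue activity shares
#'
#' The noiseless target of the efficiency scores: each promoter's activity
#' divided by the tissue's activity sum, scaled by 100. Pool composition
#' cancels out of this quantity, as it does out of the efficiency scores.
#'
#' @param truth a [screen_truth()].
#' @return Promoters x tissues matrix summing to 100 per tissue.
#' @export
true_efficiency_shares <- function(truth) {
  stopifnot(inherits(truth, "screen_truth"))
  100 * sweep(truth$activity, 2L, colSums(truth$activity), `/`)
}

#' Simulate barcode count tables for a full screen
#'
#' For each animal the pool composition is softly perturbed
#' (Dirichlet jitter) to model injection and biodistribution variability;
#' per tissue, gDNA counts are multinomial draws from that composition and
#' cDNA counts are multinomial draws proportional to the *realized* gDNA
#' proportions times the true activities - transcription happens from the
#' genomes actually delivered, which is the causal structure the
#' expression ratio assumes. Bulk expression is
#' `C = c0 * biodistribution * sum(L * activity)` with lognormal noise.
#' A library-stock sample drawn from the unperturbed pool is included.
#'
#' With `exact = TRUE` all random draws are replaced by their expected
#' values (and noise is switched off), yielding the noiseless, error-free
#' screen used for fixed-point checks.
#'
#' @param truth a [screen_truth()].
#' @param exact use exact expectations instead of random draws.
#' @return List with `counts` (named list of `barcode_counts`), `samples`
#'   (a [sample_sheet()]), `bulk` (animal_id, tissue, c_beta), and `truth`.
#' @export
simulate_counts <- function(truth, exact = FALSE) {
  stopifnot(inherits(truth, "screen_truth"))
  A <- truth$activity
  L <- truth$pool_proportions
  tissues <- colnames(A)
  promoters <- rownames(A)
  animals <- sprintf("m%d", seq_len(truth$n_animals))

  as_counts <- function(v, sample_id) {
    structure(list(sample_id = sample_id,
                   counts = stats::setNames(v, promoters),
                   qc = list(reads_seen = sum(v), reads_no_anchor = 0L,
                             reads_bc_unassigned = 0L,
                             reads_bc_ambiguous = 0L)),
              class = "barcode_counts")
  }
  draw <- function(depth, p) {
    p <- p / sum(p)
    if (exact) depth * p else as.integer(stats::rmultinom(1L, depth, p))
  }

  with_seed(truth$seed + 1L, {
    counts <- list()
    sheet <- list()
    bulk <- list()
    counts[["library_stock"]] <- as_counts(draw(truth$depth_gdna, L),
                                           "library_stock")
    sheet[[1L]] <- data.frame(sample_id = "library_stock",
                              animal_id = "pool", tissue = "pool",
                              material = "library_stock",
                              stringsAsFactors = FALSE)
    for (a in animals) {
      La <- if (exact) L else rdirichlet1(truth$dirichlet_concentration * L)
      for (tb in tissues) {
        g <- draw(truth$depth_gdna, La)
        pg <- g / sum(g)
        w <- pg * A[, tb]
        cc <- draw(truth$depth_cdna, w)
        gid <- paste(a, tb, "gDNA", sep = "_")
        cid <- paste(a, tb, "cDNA", sep = "_")
        counts[[gid]] <- as_counts(g, gid)
        counts[[cid]] <- as_counts(cc, cid)
        sheet[[length(sheet) + 1L]] <- data.frame(
          sample_id = c(gid, cid), animal_id = a, tissue = tb,
          material = c("gDNA", "cDNA"), stringsAsFactors = FALSE)
        cb <- truth$c0 * truth$biodistribution[[tb]] * sum(La * A[, tb])
        if (!exact && truth$lognormal_sd > 0) {
          cb <- cb * stats::rlnorm(1L, 0, truth$lognormal_sd)
        }
        bulk[[length(bulk) + 1L]] <- data.frame(
          animal_id = a, tissue = tb, c_beta = cb,
          stringsAsFactors = FALSE)
      }
    }
    list(counts = counts,
         samples = sample_sheet(do.call(rbind, sheet)),
         bulk = do.call(rbind, bulk),
         truth = truth)
  })
}

#' Write simulated count tables as FASTQ files
#'
#' Emits one read per counted barcode: 5' anchor + barcode + 3' anchor +
#' a fixed filler pattern, padded to the configured read length, with each
#' base independently substituted with probability `base_error`. Reads are
#' shuffled within each sample. Output is deterministic for a fixed truth
#' seed, byte for byte.
#'
#' @param counts named list of `barcode_counts` (e.g. from
#'   [simulate_counts()]).
#' @param truth the [screen_truth()] providing map, amplicon
#'   configuration, error rate, read length, and seed.
#' @param dir output directory (created if needed).
#' @param gzip write gzipped FASTQ (default `TRUE`).
#' @return Named character vector of file paths.
#' @export
simulate_fastq <- function(counts, truth, dir, gzip = TRUE) {
  stopifnot(inherits(truth, "screen_truth"))
  map <- truth$map
  config <- truth$config
  width <- truth$read_length
  min_len <- nchar(config$anchor5) + config$bc_length + nchar(config$anchor3)
  if (min_len > width) {
    stop("template overflow: anchors + barcode (", min_len,
         " nt) exceed the ", width, "-nt read length")
  }
  filler <- substr(strrep("TGCA", ceiling(width / 4)), 1L, width - min_len)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alphabet <- c("A", "C", "G", "T")
  qual <- strrep("I", width)

  templates <- stats::setNames(
    paste0(config$anchor5, map$barcode, config$anchor3, filler),
    map$promoter_id)

  paths <- character(0)
  with_seed(truth$seed + 2L, {
    for (ct in counts) {
      v <- round(ct$counts)
      reads <- rep(templates[names(v)], v)
      n <- length(reads)
      if (n > 0L) {
        reads <- reads[sample.int(n)]
        if (truth$base_error > 0) {
          nmut <- stats::rbinom(n, width, truth$base_error)
          for (i in which(nmut > 0L)) {
            pos <- sample.int(width, nmut[[i]])
            for (p in pos) {
              old <- substr(reads[[i]], p, p)
              substr(reads[[i]], p, p) <-
                sample(setdiff(alphabet, old), 1L)
            }
          }
        }
      }
      path <- file.path(dir, paste0(ct$sample_id, ".fastq",
                                    if (gzip) ".gz" else ""))
      dss <- Biostrings::DNAStringSet(unname(reads))
      names(dss) <- sprintf("%s_read%06d", ct$sample_id, seq_len(n))
      Biostrings::writeXStringSet(
        dss, filepath = path, format = "fastq",
        qualities = Biostrings::BStringSet(rep(qual, n)),
        compress = gzip)
      paths[[ct$sample_id]] <- path
    }
  })
  paths
}

#' Simulate a single-vector validation cohort
#'
#' Each selected promoter is "injected" into its own replicate animals.
#' Per animal and tissue, the true vector load is the tissue
#' biodistribution with lognormal jitter; ddPCR reports reporter and Rpp30
#' copies with independent lognormal measurement noise around
#' `G * cells` and `2 * cells`; qPCR reports housekeeper Ct around a fixed
#' level and target Ct shifted by `-log2(G * activity / c0)`, each
#' replicate with Gaussian Ct noise. Promoters with zero activity in a
#' tissue yield no amplification (missing target Ct). `exact = TRUE`
#' switches all noise off.
#'
#' @param truth a [screen_truth()].
#' @param promoters promoters to take forward (default: the first 4, as in
#'   a typical validation of top candidates).
#' @param animals_per_promoter replicate animals per construct (default 4).
#' @param exact noiseless mode.
#' @param mu_hk housekeeper Ct level (default 20 cycles).
#' @param cells nominal diploid-genome equivalents per ddPCR input
#'   (default 1e4).
#' @return List with `qpcr` and `ddpcr` data.frames in the layout expected
#'   by [single_vector_expression()].
#' @export
simulate_single_vector <- function(truth, promoters = NULL,
                                   animals_per_promoter = 4L,
                                   exact = FALSE, mu_hk = 20, cells = 1e4) {
  stopifnot(inherits(truth, "screen_truth"))
  A <- truth$activity
  if (is.null(promoters)) {
    promoters <- rownames(A)[seq_len(min(4L, nrow(A)))]
  }
  stopifnot(all(promoters %in% rownames(A)))
  tissues <- colnames(A)
  sdl <- if (exact) 0 else truth$lognormal_sd
  sdc <- if (exact) 0 else truth$ct_sd

  with_seed(truth$seed + 3L, {
    rows_q <- list(); rows_d <- list()
    for (p in promoters) {
      for (j in seq_len(animals_per_promoter)) {
        animal <- sprintf("%s_m%d", p, j)
        for (tb in tissues) {
          g_true <- truth$biodistribution[[tb]] *
            (if (sdl > 0) stats::rlnorm(1L, 0, sdl) else 1)
          eyfp <- g_true * cells *
            (if (sdl > 0) stats::rlnorm(1L, 0, sdl) else 1)
          rpp30 <- 2 * cells *
            (if (sdl > 0) stats::rlnorm(1L, 0, sdl) else 1)
          hk <- mu_hk + (if (sdc > 0) stats::rnorm(2L, 0, sdc) else c(0, 0))
          act <- A[p, tb]
          tgt <- if (act == 0) c(NA_real_, NA_real_) else {
            mu_hk - log2(g_true * act / truth$c0) +
              (if (sdc > 0) stats::rnorm(2L, 0, sdc) else c(0, 0))
          }
          rows_q[[length(rows_q) + 1L]] <- data.frame(
            animal = animal, tissue = tb, promoter = p,
            ct_target_rep1 = tgt[[1L]], ct_target_rep2 = tgt[[2L]],
            ct_hk_rep1 = hk[[1L]], ct_hk_rep2 = hk[[2L]],
            stringsAsFactors = FALSE)
          rows_d[[length(rows_d) + 1L]] <- data.frame(
            animal = animal, tissue = tb, promoter = p,
            eyfp_copies = eyfp, rpp30_copies = rpp30,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(qpcr = do.call(rbind, rows_q), ddpcr = do.call(rbind, rows_d))
  })
}

#' Score recovery of a pipeline run against simulator ground truth
#'
#' Compares estimated efficiency-type scores with the true within-tissue
#' activity shares: per-tissue Spearman correlation, whether the top
#' promoter was identified, and the mean absolute score error. The pooled
#' Spearman correlation over all cells and the number of tissues with
#' top-promoter agreement are attached as attributes.
#'
#' @param estimated promoters x tissues matrix (or a `score_matrix`, whose
#'   `mean`/`values` are used).
#' @param truth a [screen_truth()].
#' @return data.frame with columns `tissue`, `spearman`, `top1_match`,
#'   `mae`; attributes `overall_spearman` and `top1_agreement`.
#' @export
recovery_report <- function(estimated, truth) {
  if (inherits(estimated, "score_matrix")) {
    estimated <- estimated$mean %||% estimated$values
  }
  ref <- true_efficiency_shares(truth)
  if (!identical(dim(estimated), dim(ref)) ||
      !identical(rownames(estimated), rownames(ref)) ||
      !identical(colnames(estimated), colnames(ref))) {
    stop("estimated and truth promoter x tissue indices do not match")
  }
  tissues <- colnames(ref)
  per <- data.frame(
    tissue = tissues,
    spearman = vapply(tissues, function(tb) {
      stats::cor(estimated[, tb], ref[, tb], method = "spearman",
                 use = "complete.obs")
    }, 0),
    top1_match = vapply(tissues, function(tb) {
      which.max(estimated[, tb]) == which.max(ref[, tb])
    }, TRUE),
    mae = vapply(tissues, function(tb) {
      mean(abs(estimated[, tb] - ref[, tb]), na.rm = TRUE)
    }, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  ok <- is.finite(estimated) & is.finite(ref)
  attr(per, "overall_spearman") <-
    stats::cor(estimated[ok], ref[ok], method = "spearman")
  attr(per, "top1_agreement") <- sum(per$top1_match)
  per
}

#' Per-tissue top-promoter agreement between two score sets
#'
#' @param e1,e2 promoters x tissues matrices (or `score_matrix` objects)
#'   over the same index.
#' @return Named logical vector per tissue.
#' @export
top_promoter_agreement <- function(e1, e2) {
  pick <- function(x) {
    if (inherits(x, "score_matrix")) x$mean %||% x$values else x
  }
  e1 <- pick(e1); e2 <- pick(e2)
  if (!setequal(rownames(e1), rownames(e2)) ||
      !setequal(colnames(e1), colnames(e2))) {
    stop("score matrices do not share a promoter x tissue index")
  }
  e2 <- e2[rownames(e1), colnames(e1), drop = FALSE]
  vapply(colnames(e1), function(tb) {
    which.max(e1[, tb]) == which.max(e2[, tb])
  }, TRUE)
}
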