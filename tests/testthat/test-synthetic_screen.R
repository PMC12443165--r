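small_truth <- function(...) {
  args <- utils::modifyList(
    list(n_promoters = 8, tissues = c("liver", "heart", "brain"),
         n_animals = 2, depth_gdna = 2e4, depth_cdna = 2e4),
    list(...))
  do.call(screen_truth, args)
}

test_that("flat activity yields cDNA proportions matching gDNA proportions", {
  A <- matrix(1, nrow = 8, ncol = 3)
  tr <- small_truth(activity = A, seed = 2)
  sim <- simulate_counts(tr)
  g <- sim$counts[["m1_liver_gDNA"]]$counts
  cc <- sim$counts[["m1_liver_cDNA"]]$counts
  pg <- g / sum(g)
  pc <- cc / sum(cc)
  expect_true(all(abs(pc - pg) <= 3 * sqrt(pg * (1 - pg) / sum(cc)) + 1e-12))
})

test_that("a silent promoter never yields cDNA reads", {
  A <- matrix(1, nrow = 8, ncol = 3)
  A[5, ] <- 0
  tr <- small_truth(activity = A, seed = 3)
  sim <- simulate_counts(tr)
  cdna <- grep("cDNA", names(sim$counts), value = TRUE)
  for (s in cdna) expect_identical(sim$counts[[s]]$counts[[5]], 0L)
})

test_that("identical seeds reproduce identical counts and FASTQ bytes", {
  tr <- small_truth(seed = 9, depth_gdna = 3e3, depth_cdna = 3e3)
  s1 <- simulate_counts(tr)
  s2 <- simulate_counts(tr)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$bulk, s2$bulk)
  d1 <- tempfile(); d2 <- tempfile()
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  p1 <- simulate_fastq(s1$counts[1:4], tr, d1)
  p2 <- simulate_fastq(s2$counts[1:4], tr, d2)
  for (k in seq_along(p1)) {
    expect_identical(readBin(p1[[k]], "raw", 5e6), readBin(p2[[k]], "raw", 5e6))
  }
})

test_that("error-free FASTQ reproduces the count tables exactly", {
  tr <- small_truth(seed = 6, base_error = 0, depth_gdna = 3e3,
                    depth_cdna = 3e3)
  sim <- simulate_counts(tr)
  d <- tempfile()
  on.exit(unlink(d, recursive = TRUE))
  paths <- simulate_fastq(sim$counts[1:5], tr, d)
  for (s in names(paths)) {
    ct <- count_sample(paths[[s]], tr$map, tr$config, sample_id = s)
    expect_identical(as.integer(ct$counts),
                     as.integer(sim$counts[[s]]$counts))
    expect_identical(ct$qc$reads_no_anchor + ct$qc$reads_bc_unassigned +
                       ct$qc$reads_bc_ambiguous, 0L)
  }
})

test_that("read losses match the closed-form survival probability", {
  tr <- screen_truth(n_promoters = 8, tissues = c("liver", "heart"),
                     n_animals = 1, depth_gdna = 1e4, depth_cdna = 1e4,
                     base_error = 0.01, seed = 9)
  sim <- simulate_counts(tr)
  d <- tempfile()
  on.exit(unlink(d, recursive = TRUE))
  s <- "m1_liver_gDNA"
  path <- simulate_fastq(sim$counts[s], tr, d)
  ct <- count_sample(path[[1]], tr$map, tr$config, sample_id = s)
  # closed form: a read survives if each of anchor5, anchor3, and barcode
  # carries at most one substitution (1-mismatch tolerance everywhere)
  p_le1 <- function(len, e) pbinom(1, len, e)
  e <- tr$base_error
  p_surv <- p_le1(nchar(tr$config$anchor5), e) *
    p_le1(nchar(tr$config$anchor3), e) *
    p_le1(tr$config$bc_length, e)
  n <- sum(sim$counts[[s]]$counts)
  lost <- n - sum(ct$counts)
  expect_lt(abs(lost - n * (1 - p_surv)),
            3 * sqrt(n * p_surv * (1 - p_surv)))
})

test_that("gDNA proportions converge to the pool proportions with depth", {
  devs <- vapply(c(1e3, 1e4, 1e5), function(depth) {
    tr <- screen_truth(n_promoters = 10, tissues = "liver", n_animals = 1,
                       depth_gdna = depth, depth_cdna = depth, seed = 29,
                       dirichlet_concentration = 1e12)
    sim <- simulate_counts(tr)
    g <- sim$counts[["m1_liver_gDNA"]]$counts
    max(abs(g / sum(g) - tr$pool_proportions))
  }, 0)
  expect_lt(devs[[3]], devs[[1]])
  expect_lt(devs[[3]], 0.01)
})

test_that("the noiseless simulator is an exact fixed point of the pipeline", {
  tr <- small_truth(seed = 12, base_error = 0, ct_sd = 0)
  sim <- simulate_counts(tr, exact = TRUE)
  res <- quantify_screen(sim$counts, sim$samples, sim$bulk)
  shares <- true_efficiency_shares(tr)
  expect_lt(max(abs(res$efficiency_mean$mean - shares) / shares), 1e-9)

  sv <- simulate_single_vector(tr, promoters = rownames(tr$activity),
                               animals_per_promoter = 2, exact = TRUE)
  x <- single_vector_expression(sv$qpcr, sv$ddpcr)
  val <- validation_scores(x)
  expect_lt(max(abs(val$efficiency$values - shares) / shares), 1e-9)
  # Q recovers activity / c0 exactly
  A <- tr$activity
  rel <- mapply(function(p, tb, q) abs(q - A[p, tb] / tr$c0) / (A[p, tb]),
                x$promoter, x$tissue, x$q)
  expect_lt(max(rel), 1e-9)
})

test_that("single-vector simulation behaves at zero and finite noise", {
  A <- matrix(c(2, 1, 0, 4, 1, 1), nrow = 2, byrow = TRUE)
  tr <- screen_truth(n_promoters = 2, tissues = c("liver", "heart", "brain"),
                     n_animals = 1, activity = A, seed = 5)
  sv <- simulate_single_vector(tr, promoters = c("P01", "P02"),
                               animals_per_promoter = 4)
  # zero activity: no amplification, Q masked
  x <- suppressMessages(single_vector_expression(sv$qpcr, sv$ddpcr))
  silent <- x[x$promoter == "P01" & x$tissue == "brain", ]
  expect_true(all(is.na(silent$q)))
  # mean recovered Q within 3 SE of the truth (activity / c0)
  for (tb in c("liver", "heart")) {
    for (p in c("P01", "P02")) {
      q <- x$q[x$promoter == p & x$tissue == tb]
      se <- sd(q) / sqrt(length(q))
      expect_lt(abs(mean(q) - tr$activity[p, tb]), 3 * se + 1e-12)
    }
  }
})

test_that("recovery metrics behave at the perfect and null extremes", {
  tr <- small_truth(seed = 14)
  shares <- true_efficiency_shares(tr)
  perfect <- recovery_report(shares, tr)
  expect_equal(perfect$spearman, rep(1, 3))
  expect_equal(attr(perfect, "top1_agreement"), 3)
  expect_equal(perfect$mae, rep(0, 3))

  set.seed(15)
  perm <- shares[sample(nrow(shares)), ]
  rownames(perm) <- rownames(shares)
  null <- recovery_report(perm, tr)
  expect_lt(abs(attr(null, "overall_spearman")), 0.6)

  bad <- shares[-1, ]
  expect_error(recovery_report(bad, tr), "do not match")
})
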