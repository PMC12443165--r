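# Two-tissue, three-promoter worked example used in several tests; all
# expected values recomputed from scratch inside the tests.
worked_example <- function() {
  proms <- c("A", "B", "C")
  counts <- list(
    m1_liver_gDNA = make_counts("m1_liver_gDNA",
                                c(A = 200, B = 300, C = 500)),
    m1_liver_cDNA = make_counts("m1_liver_cDNA",
                                c(A = 600, B = 300, C = 100)),
    m1_heart_gDNA = make_counts("m1_heart_gDNA",
                                c(A = 250, B = 250, C = 500)),
    m1_heart_cDNA = make_counts("m1_heart_cDNA",
                                c(A = 250, B = 250, C = 500)))
  samples <- data.frame(
    sample_id = names(counts),
    animal_id = "m1",
    tissue = rep(c("liver", "heart"), each = 2),
    material = rep(c("gDNA", "cDNA"), 2))
  bulk <- data.frame(animal_id = "m1", tissue = c("liver", "heart"),
                     c_beta = c(2, 0.5))
  list(counts = counts, samples = samples, bulk = bulk, promoters = proms)
}

test_that("proportions divide by assigned totals and flag shallow samples", {
  expect_equal(proportions(c(A = 50, B = 50), min_reads = 10),
               c(A = 0.5, B = 0.5))
  expect_equal(proportions(c(A = 100), min_reads = 10), c(A = 1.0))
  expect_warning(
    out <- proportions(make_counts("shallow", c(A = 5, B = 5))),
    "flagged failed")
  expect_null(out)
  # multinomial sampling: each estimate within 3 sigma of the truth
  p <- c(0.5, 0.3, 0.15, 0.04, 0.01)
  names(p) <- paste0("P", 1:5)
  set.seed(61)
  draw <- stats::rmultinom(1, 1e5, p)[, 1]
  names(draw) <- names(p)
  est <- proportions(draw)
  expect_true(all(abs(est - p) <= 3 * sqrt(p * (1 - p) / 1e5)))
})

test_that("normalized expression is the cDNA/gDNA ratio times bulk expression", {
  p <- matrix(c(0.2, 0.8), ncol = 1, dimnames = list(c("A", "B"), "t"))
  ne <- normalized_expression(p, p, 1)
  expect_equal(unname(ne$R[, 1]), c(1, 1))
  ne2 <- normalized_expression(matrix(0.5), matrix(0.25), 0.2)
  expect_equal(ne2$R[1, 1], 0.4)
  # gDNA zero is masked, not infinite
  pg <- matrix(c(0, 1), ncol = 1); pc <- matrix(c(0.5, 0.5), ncol = 1)
  ne3 <- normalized_expression(pc, pg, 1)
  expect_true(is.na(ne3$R[1, 1]) && is.finite(ne3$R[2, 1]))
})

test_that("unpaired samples and low-count gDNA cells are handled explicitly", {
  ex <- worked_example()
  ex$counts$m1_heart_gDNA <- NULL
  ex$samples <- ex$samples[ex$samples$sample_id != "m1_heart_gDNA", ]
  expect_error(sample_sheet(ex$samples), "m1.*heart")

  ex2 <- worked_example()
  ex2$counts$m1_liver_gDNA$counts[["A"]] <- 3 # below the 10-read floor
  res <- quantify_screen(ex2$counts, ex2$samples, ex2$bulk, min_reads = 100)
  expect_true(is.na(res$ne$R["A", "m1|liver"]))
  expect_false(anyNA(res$ne$R["B", ]))
})

test_that("the worked example reproduces hand-computed R, E, and S exactly", {
  ex <- worked_example()
  res <- quantify_screen(ex$counts, ex$samples, ex$bulk, min_reads = 100)

  # independent arithmetic, written out term by term
  r_liver <- c(A = (600 / 1000) / (200 / 1000) * 2,
               B = (300 / 1000) / (300 / 1000) * 2,
               C = (100 / 1000) / (500 / 1000) * 2)
  r_heart <- c(A = 0.25 / 0.25 * 0.5, B = 0.25 / 0.25 * 0.5,
               C = 0.5 / 0.5 * 0.5)
  expect_equal(res$ne$R[, "m1|liver"], r_liver)
  expect_equal(res$ne$R[, "m1|heart"], r_heart)

  e_liver <- 100 * r_liver / sum(r_liver)
  e_heart <- 100 * r_heart / sum(r_heart)
  expect_equal(res$efficiency$values[, "m1|liver"], e_liver)
  expect_equal(res$efficiency$values[, "m1|heart"], e_heart)
  expect_equal(unname(e_liver), c(100 * 6 / 8.4, 100 * 2 / 8.4,
                                  100 * 0.4 / 8.4))

  s_expected <- t(vapply(ex$promoters, function(p) {
    v <- c(r_liver[[p]], r_heart[[p]])
    100 * v / sum(v)
  }, numeric(2)))
  expect_equal(unname(res$specificity$values),
               unname(s_expected))
  expect_equal(unname(res$specificity$values["A", ]),
               c(100 * 6 / 6.5, 100 * 0.5 / 6.5))
})

test_that("efficiency ignores bulk scaling while specificity follows it", {
  ex <- worked_example()
  res <- quantify_screen(ex$counts, ex$samples, ex$bulk, min_reads = 100)
  ex10 <- ex
  ex10$bulk$c_beta[ex10$bulk$tissue == "liver"] <-
    10 * ex10$bulk$c_beta[ex10$bulk$tissue == "liver"]
  res10 <- quantify_screen(ex10$counts, ex10$samples, ex10$bulk,
                           min_reads = 100)
  expect_equal(res10$efficiency$values, res$efficiency$values)
  # liver specificity strictly increases for every promoter
  expect_true(all(res10$specificity$values[, "m1|liver"] >
                    res$specificity$values[, "m1|liver"]))
  expect_true(all(res10$specificity$values[, "m1|heart"] <
                    res$specificity$values[, "m1|heart"]))
})

test_that("scores are invariant to sequencing depth scaling", {
  ex <- worked_example()
  res <- quantify_screen(ex$counts, ex$samples, ex$bulk, min_reads = 100)
  exk <- ex
  exk$counts <- lapply(exk$counts, function(ct) {
    make_counts(ct$sample_id, ct$counts * 7L)
  })
  resk <- quantify_screen(exk$counts, exk$samples, exk$bulk, min_reads = 100)
  expect_equal(resk$ne$R, res$ne$R)
  expect_equal(resk$efficiency$values, res$efficiency$values)
  expect_equal(resk$specificity$values, res$specificity$values)
})

test_that("score normalization invariants hold on simulated screens", {
  tr <- screen_truth(n_promoters = 12,
                     tissues = c("liver", "heart", "brain", "muscle", "fat"),
                     n_animals = 3, depth_gdna = 2e4, depth_cdna = 2e4,
                     seed = 17)
  sim <- simulate_counts(tr)
  res <- quantify_screen(sim$counts, sim$samples, sim$bulk)
  E <- res$efficiency$values
  expect_true(all(abs(colSums(E, na.rm = TRUE) - 100) < 1e-9))
  expect_true(all(E >= 0 & E <= 100 + 1e-9, na.rm = TRUE))
  S <- res$specificity$values
  for (a in unique(res$specificity$colData$animal)) {
    cols <- res$specificity$colData$animal == a
    expect_true(all(abs(rowSums(S[, cols], na.rm = TRUE) - 100) < 1e-9))
  }
  expect_true(all(S >= 0 & S <= 100 + 1e-9, na.rm = TRUE))
})

test_that("replicate aggregation returns mean, SD and n per cell", {
  ex <- worked_example()
  # duplicate the animal: identical scores, SD 0, n 2
  ex2 <- ex
  for (nm in names(ex$counts)) {
    nm2 <- sub("m1", "m2", nm)
    ex2$counts[[nm2]] <- make_counts(nm2, ex$counts[[nm]]$counts)
  }
  sheet2 <- ex$samples
  sheet2$sample_id <- sub("m1", "m2", sheet2$sample_id)
  sheet2$animal_id <- "m2"
  ex2$samples <- rbind(ex$samples, sheet2)
  ex2$bulk <- rbind(ex$bulk, transform(ex$bulk, animal_id = "m2"))
  res <- quantify_screen(ex2$counts, ex2$samples, ex2$bulk, min_reads = 100)
  agg <- aggregate_replicates(res$efficiency)
  expect_equal(unname(agg$sd[!is.na(agg$sd)]),
               rep(0, sum(!is.na(agg$sd))))
  expect_true(all(agg$n == 2))
  expect_equal(agg$mean, res$efficiency$values[, 1:2],
               ignore_attr = "dimnames")

  # closed form: mean(40, 60) = 50, sd = sqrt(200)
  m <- matrix(c(40, 60), nrow = 1,
              dimnames = list("P", c("m1|t", "m2|t")))
  ne <- normalized_expression(m, m * 0 + 1, c(1, 1),
                              animals = c("m1", "m2"), tissues = c("t", "t"))
  sm <- promoscreen:::new_score_matrix(m, "efficiency", ne$colData)
  agg2 <- aggregate_replicates(sm)
  expect_equal(agg2$mean[1, 1], 50)
  expect_equal(agg2$sd[1, 1], sqrt(200))

  # index mismatch across animals is an error
  a <- res$efficiency
  b <- res$efficiency
  rownames(b$values) <- c("X", "Y", "Z")
  expect_error(aggregate_replicates(list(a, b)), "index mismatch")
})
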