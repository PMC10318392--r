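test_that("count-threshold caller applies the allele-ratio bands", {
  expect_identical(count_threshold_call(counts_tab(1, 20), 0.1), 0L)
  expect_identical(count_threshold_call(counts_tab(10, 20), 0.45), 1L)
  expect_identical(count_threshold_call(counts_tab(10, 20), 0.05), 1L)
  # band boundary belongs to the heterozygote
  expect_identical(count_threshold_call(counts_tab(2, 20), 0.1), 1L)
  expect_identical(count_threshold_call(counts_tab(18, 20), 0.1), 1L)
  expect_identical(count_threshold_call(counts_tab(19, 20), 0.1), 2L)
  expect_identical(count_threshold_call(counts_tab(0, 0), 0.1),
                   NA_integer_)
  expect_error(count_threshold_call(counts_tab(1, 10), 0.6), "t")
  # band nesting: raising t narrows the het band monotonically
  set.seed(51)
  cts <- counts_tab(rbinom(500, 30, runif(500)), rep(30, 500))
  het_n <- vapply(c(0.001, 0.05, 0.1, 0.2),
                  function(t) sum(count_threshold_call(cts, t) == 1L),
                  numeric(1))
  expect_true(all(diff(het_n) <= 0))
})

test_that("concordance recovers planted error counts exactly", {
  truth <- setNames(rep(0:2, each = 10), paste0("s", 1:30))
  calls <- data.frame(site_id = names(truth), hard_call = unname(truth),
                      n_total = rep(20L, 30))
  cb <- concordance_by_genotype(calls, truth, min_depth = 10)
  expect_equal(cb$by_genotype$accuracy, rep(1, 3))
  expect_equal(cb$het_to_hom + cb$hom_to_het, 0)

  # single planted het -> hom error
  calls2 <- calls
  calls2$hard_call[calls2$site_id == "s11"] <- 0L
  cb2 <- concordance_by_genotype(calls2, truth)
  expect_equal(cb2$by_genotype$accuracy[2], 0.9)
  expect_equal(cb2$het_to_hom, 1)
  expect_equal(cb2$hom_to_het, 0)

  # randomized planted errors recovered exactly
  set.seed(52)
  for (r in 1:10) {
    e_th <- sample(0:5, 1) # het -> hom
    e_hh <- sample(0:5, 1) # hom -> het
    calls3 <- calls
    het_idx <- sample(which(truth == 1L), e_th)
    hom_idx <- sample(which(truth != 1L), e_hh)
    calls3$hard_call[het_idx] <- sample(c(0L, 2L), e_th, replace = TRUE)
    calls3$hard_call[hom_idx] <- 1L
    cb3 <- concordance_by_genotype(calls3, truth)
    expect_identical(cb3$het_to_hom, as.integer(e_th))
    expect_identical(cb3$hom_to_het, as.integer(e_hh))
  }
  expect_error(concordance_by_genotype(rbind(calls, calls[1, ]), truth),
               "ambiguous")
})

test_that("missing calls and depth filters conserve site totals", {
  truth <- setNames(rep(0:2, each = 20), paste0("s", 1:60))
  set.seed(53)
  calls <- data.frame(site_id = names(truth),
                      hard_call = unname(truth),
                      n_total = sample(5:40, 60, replace = TRUE))
  calls$hard_call[sample(60, 8)] <- NA_integer_
  for (d in c(1, 10, 20, 30)) {
    cb <- concordance_by_genotype(calls, truth, min_depth = d)
    tot <- sum(cb$by_genotype$concordant) + sum(cb$by_genotype$discordant) +
      sum(cb$by_genotype$missing)
    expect_equal(tot, sum(calls$n_total >= d))
    expect_equal(tot, cb$n_truth_overlap)
    # stratified accuracies recombine into the aggregate
    w <- cb$by_genotype$concordant + cb$by_genotype$discordant
    ok <- w > 0
    expect_equal(sum(cb$by_genotype$accuracy[ok] * w[ok]) / sum(w),
                 cb$accuracy)
  }
})

test_that("accuracy-by-depth sweep matches brute-force counting", {
  truth <- setNames(rep(0:2, each = 20), paste0("s", 1:60))
  set.seed(54)
  calls <- data.frame(site_id = names(truth), hard_call = unname(truth),
                      n_total = sample(5:40, 60, replace = TRUE))
  # plant errors only at depth < 20
  shallow <- which(calls$n_total < 20)
  calls$hard_call[shallow[1:3]] <- (calls$hard_call[shallow[1:3]] + 1L) %% 3L
  tab <- accuracy_vs_depth(calls, truth, depth_grid = c(10, 20))
  expect_true(tab$accuracy[2] > tab$accuracy[1])
  expect_true(all(diff(tab$n_calls) <= 0))
  for (i in seq_len(nrow(tab)))
    expect_equal(tab$n_calls[i],
                 sum(calls$n_total >= tab$min_depth[i] &
                     !is.na(calls$hard_call)))
  expect_error(accuracy_vs_depth(calls, truth, integer(0)), "depth_grid")
  one <- accuracy_vs_depth(calls[-shallow[1:3], ], truth, 1)
  expect_equal(one$accuracy, 1)
})

test_that("dosage concordance rounds halves away from zero", {
  truth <- setNames(c(0L, 1L, 2L), c("a", "b", "c"))
  d <- data.frame(site_id = c("a", "b", "c"), dosage = c(0, 1, 2))
  expect_equal(dosage_concordance(d, truth), 1)
  d2 <- data.frame(site_id = c("b", "b2"), dosage = c(1.49, 1.51))
  truth2 <- setNames(c(1L, 1L), c("b", "b2"))
  expect_equal(dosage_concordance(d2, truth2), 0.5)
  # the half itself rounds up (away from zero)
  d3 <- data.frame(site_id = "b", dosage = 0.5)
  expect_equal(dosage_concordance(d3, truth["b"]), 1)
  expect_error(dosage_concordance(data.frame(site_id = "a", dosage = 2.3),
                                  truth), "dosage")
})
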