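test_that("hypergeometric tail matches hand cases and the exact oracle", {
  # P(X >= 0) = 1 whatever the configuration
  expect_identical(hypergeometric_pvalue(0, 5, 10, 100), 1)
  # query equal to the whole background forces the overlap
  expect_identical(hypergeometric_pvalue(7, 20, 7, 20), 1)
  # frozen value computed with the exact integer-arithmetic oracle:
  # sum_{i=3}^{5} C(10,i) C(90,5-i) / C(100,5) = 499752 / 75287520
  expect_equal(hypergeometric_pvalue(3, 5, 10, 100), 499752 / 75287520,
               tolerance = 1e-14)
})

test_that("hypergeometric domain violations name the offending argument", {
  expect_error(hypergeometric_pvalue(6, 5, 10, 100), "`k`")
  expect_error(hypergeometric_pvalue(1, 101, 10, 100), "`n`")
  expect_error(hypergeometric_pvalue(1, 5, 101, 100), "`K`")
  expect_error(hypergeometric_pvalue(-1, 5, 10, 100), "`k`")
  expect_error(hypergeometric_pvalue(0.5, 5, 10, 100), "`k`")
})

test_that("p-value is monotone in k and in K on a grid", {
  N <- 80L
  for (n in c(5L, 20L, 40L)) {
    for (K in c(4L, 15L, 60L)) {
      kmax <- min(n, K)
      p <- hypergeometric_pvalue(0:kmax, n, K, N)
      expect_true(all(diff(p) <= 1e-15), # non-increasing in k
                  label = sprintf("monotone in k (n=%d K=%d)", n, K))
    }
    for (k in c(1L, 3L)) {
      Ks <- k:(N - n + k)
      Ks <- Ks[Ks >= k & Ks <= N]
      p <- hypergeometric_pvalue(k, n, Ks, N)
      expect_true(all(diff(p) >= -1e-12), # non-decreasing in K
                  label = sprintf("monotone in K (n=%d k=%d)", n, k))
    }
  }
})

test_that("BH adjustment matches the literal step-up and stats::p.adjust", {
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  # frozen via the literal step-up: every m*p/j equals 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH never rejects more than uncorrected testing", {
  set.seed(23)
  for (i in 1:20) {
    p <- runif(30)^2
    alpha <- runif(1, 0.01, 0.2)
    expect_lte(sum(bh_adjust(p) <= alpha), sum(p <= alpha))
  }
})

make_test_collection <- function(members, type = "pathway") {
  gene_set_collection(
    tibble::tibble(category_id = names(members),
                   name = names(members),
                   genes = unname(members)),
    category_type = type)
}

test_that("run_ora: disjoint query gives p = 1 everywhere, nothing significant", {
  universe <- sprintf("G%03d", 1:100)
  coll <- make_test_collection(list(c1 = universe[1:10], c2 = universe[11:25]))
  res <- run_ora(universe[90:99], coll, background = universe)
  expect_equal(res$k, c(0L, 0L))
  expect_equal(res$p_value, c(1, 1))
  expect_false(any(res$significant))
})

test_that("run_ora recovers a planted category as top hit", {
  universe <- sprintf("G%04d", 1:1000)
  query <- universe[1:10]
  planted <- c(universe[1:8], universe[101:112])     # 8/10 query, size 20
  decoys <- lapply(1:9, function(i) universe[(200 + 30 * i):(219 + 30 * i)])
  names(decoys) <- sprintf("decoy%02d", 1:9)
  coll <- make_test_collection(c(list(planted = planted), decoys))
  res <- run_ora(query, coll, background = universe, fdr_threshold = 0.05)
  expect_equal(res$category_id[[1]], "planted")
  expect_true(res$significant[[1]])
  # p-value equals the exact oracle for k=8, n=10, K=20, N=1000, and
  # BH with m = 10 tested categories cannot lift it above 0.05
  expect_equal(nrow(res), 10L)
  p_oracle <- sum(stats::dhyper(8:10, 20, 980, 10))
  expect_equal(res$p_value[[1]], p_oracle, tolerance = 1e-12)
  expect_equal(res$fdr[[1]], bh_adjust(res$p_value)[[1]])
})

test_that("run_ora: identical member sets get identical p and fdr", {
  universe <- sprintf("G%03d", 1:200)
  same <- universe[1:15]
  coll <- make_test_collection(list(a = same, b = same, c = same))
  res <- run_ora(universe[1:20], coll, background = universe)
  expect_equal(length(unique(res$p_value)), 1L)
  expect_equal(length(unique(res$fdr)), 1L)
})

test_that("run_ora restricts to background and applies size filters", {
  universe <- sprintf("G%03d", 1:50)
  coll <- make_test_collection(list(
    tiny = universe[1:2],                     # below min size
    ok = universe[1:10],
    off_bg = c(universe[1:5], "X1", "X2")     # trimmed to in-background part
  ))
  expect_message(
    res <- run_ora(c(universe[1:5], "NOT_THERE"), coll,
                   background = universe, min_category_size = 3),
    "dropped 1 query gene")
  expect_setequal(res$category_id, c("ok", "off_bg"))
  expect_equal(res$K[res$category_id == "off_bg"], 5L)
  expect_equal(res$n, rep(5L, 2))
  expect_error(run_ora(c("Z1", "Z2"), coll, background = universe),
               "no query genes in background")
})

test_that("results are ordered by p-value with id tie-breaks and export as TSV", {
  universe <- sprintf("G%03d", 1:100)
  coll <- make_test_collection(list(
    b_set = universe[1:10], a_set = universe[1:10], other = universe[50:60]))
  res <- run_ora(universe[1:10], coll, background = universe)
  expect_equal(res$category_id[1:2], c("a_set", "b_set"))

  f <- tempfile(fileext = ".tsv")
  write_ora_tsv(res, f)
  back <- utils::read.delim(f)
  expect_equal(back$category_id, res$category_id)
  expect_equal(back$p_value, res$p_value, tolerance = 1e-6)
  expect_equal(back$overlap_genes[[1]],
               paste(sort(res$overlap_genes[[1]]), collapse = ","))
})
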