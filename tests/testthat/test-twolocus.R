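test_that("balanced penetrance applies the within-class standardization", {
  # cell 1: p1 = 0.2, p0 = 0.1 -> 2/3
  cc <- c(20, 80, rep(0, 7)); nn <- c(10, 90, rep(0, 7))
  bp <- balanced_penetrance(pair_table(cc, nn))
  expect_equal(bp$values[1, 1], 2 / 3)
  expect_false(bp$occupied[2, 2])
  expect_true(is.na(bp$values[2, 2]))
  # identical case/control proportions -> all 0.5
  bp2 <- balanced_penetrance(pair_table(c(2, 4, 6, 8, 0, 0, 0, 0, 0),
                                        c(1, 2, 3, 4, 0, 0, 0, 0, 0)))
  expect_true(all(bp2$values[!is.na(bp2$values)] == 0.5))
  # invariant to duplicating every control
  set.seed(21)
  cc <- rmultinom(1, 200, runif(9))[, 1]; nn <- rmultinom(1, 150, runif(9))[, 1]
  expect_equal(balanced_penetrance(pair_table(cc, nn))$values,
               balanced_penetrance(pair_table(cc, 2 * nn))$values)
})

test_that("discretize forces rare cells low and thresholds at 0.5", {
  cc <- c(995, 5, rep(0, 7))     # cell 2: 0.5% in cases
  nn <- c(997, 3, rep(0, 7))     # 0.3% in controls, penetrance 5/8 > .5
  m <- discretize(balanced_penetrance(pair_table(cc, nn)))
  expect_equal(m$cells[1, 2], 0L)                  # rare -> low
  # high balanced penetrance on the occupied common cells -> all high
  # (within-class proportions each sum to 1, so "all cells high" needs
  # the control mass to sit elsewhere)
  m2 <- discretize(balanced_penetrance(
    pair_table(c(100, 100, 100, 100, 0, 0, 0, 0, 0),
               c(2, 2, 2, 2, 92, 0, 0, 0, 0))))
  expect_equal(as.vector(t(m2$cells))[1:4], rep(1L, 4))
  expect_equal(as.vector(t(m2$cells))[5], 0L)
})

test_that("canonical class is constant on orbits over all 512 tables", {
  for (code in 0:511) {
    cells <- epistax:::code_to_cells(code)
    id <- canonical_class(cells)
    transforms <- list(cells, cells[3:1, ], cells[, 3:1], cells[3:1, 3:1],
                       t(cells), t(cells)[3:1, ], t(cells)[, 3:1],
                       t(cells)[3:1, 3:1])
    for (tr in transforms) expect_identical(canonical_class(tr), id)
  }
})

test_that("orbit sizes divide the group order and sum to 512", {
  ids <- vapply(0:511, canonical_class, numeric(1))
  sizes <- table(ids)
  expect_true(all(8 %% as.numeric(sizes) == 0 |
                    as.numeric(sizes) %% 1 == 0 & 8 %% as.numeric(sizes) == 0))
  expect_equal(sum(sizes), 512)
  # with complementation, group order 16
  ids16 <- vapply(0:511, function(k) canonical_class(k, TRUE), numeric(1))
  expect_true(all(16 %% as.numeric(table(ids16)) == 0))
})

test_that("class counts match the published 100 / 50", {
  expect_identical(count_model_classes(include_complement = FALSE), 100L)
  expect_identical(count_model_classes(include_complement = TRUE), 50L)
  # without excluding constants: 102 / 51 raw orbits
  expect_identical(count_model_classes(FALSE, exclude_constant = FALSE), 102L)
  expect_identical(count_model_classes(TRUE, exclude_constant = FALSE), 51L)
})

test_that("discretize commutes with locus swap up to canonicalization", {
  set.seed(22)
  for (r in 1:10) {
    cc <- rmultinom(1, 300, runif(9))[, 1]; nn <- rmultinom(1, 300, runif(9))[, 1]
    swap <- function(x) as.numeric(matrix(x, 3, 3, byrow = TRUE))
    m1 <- discretize(balanced_penetrance(pair_table(cc, nn)))
    m2 <- discretize(balanced_penetrance(pair_table(swap(cc), swap(nn))))
    expect_identical(m1$class_id, m2$class_id)
  }
})

test_that("class distribution recovers planted class fractions", {
  # trivial cases
  one <- class_distribution(rep(7, 20), k_grid = c(5, 20))
  expect_true(all(one$fraction == 1))
  two <- class_distribution(rep(c(1, 1, 1, 2), 25), k_grid = 100)
  expect_equal(two$fraction[two$class_id == 1], 0.75)
  # multinomial draw recovered within 3 SE at k = n
  set.seed(23)
  draws <- sample(c(7, 15, 99), 400, TRUE, prob = c(0.4, 0.3, 0.3))
  cd <- class_distribution(draws, k_grid = 400)
  for (cl in c(7, 15, 99)) {
    target <- c(`7` = 0.4, `15` = 0.3, `99` = 0.3)[as.character(cl)]
    se <- sqrt(target * (1 - target) / 400)
    expect_lt(abs(cd$fraction[cd$class_id == cl] - target), 3 * se)
  }
  expect_error(class_distribution(numeric(0)), "no models")
})

test_that("rare-threshold sweep barely moves the class distribution", {
  mod <- penetrance_from_cells(c(5, 6, 8, 9), 0.08, 0.005, 0.35, 0.35)
  cfg <- sim_config(n_cases = 500, n_controls = 500, n_blocks = 4,
                    snps_per_block = 3,
                    planted_models = list(list(snp_a = 2, snp_b = 8,
                                               model = mod)),
                    prevalence = 0.01, seed = 24)
  st <- simulate_cohort(cfg)
  sc <- exhaustive_scan(st)
  top <- sc[order(sc$log10_p_raw)[1:20], ]
  dist_at <- function(rare) {
    ids <- vapply(seq_len(nrow(top)), function(i) {
      tb <- pair_contingency(st, top$snp_a[i], top$snp_b[i])
      discretize(balanced_penetrance(tb), rare_freq = rare)$class_id
    }, numeric(1))
    tab <- table(ids)
    setNames(as.numeric(tab) / length(ids), names(tab))
  }
  base <- dist_at(0.01)
  for (rare in c(0, 0.03, 0.05, 0.07)) {
    d <- dist_at(rare)
    cls <- union(names(base), names(d))
    diffs <- abs(ifelse(is.na(d[cls]), 0, d[cls]) -
                   ifelse(is.na(base[cls]), 0, base[cls]))
    expect_lt(max(diffs), 0.25, label = paste("rare =", rare))
  }
})
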