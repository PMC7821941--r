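small_sizes <- list(n_sobol = 64, r_morris = 10, n_fast = 129,
                    n_rbd = 256, n_dgsm = 64, n_dmim = 512)

test_that("batch evaluation is consistent with the scenario pipeline", {
  for (nm in c("scenario1", "scenario4")) {
    p <- load_scenario(nm)
    reg <- acbm_parameters()
    X <- matrix(unlist(p[reg$parameter]), nrow = 1,
                dimnames = list(NULL, reg$parameter))
    expect_equal(as.numeric(evaluate_model_batch(X, base = p)),
                 cost_breakdown(nm)$min_price, info = nm)
  }
})

test_that("batch evaluation is an elementwise map", {
  X <- cbind(maturation_time = c(100, 200, 300, 240),
             fgf2_cost = c(1e6, 2e6, 0, 2.05e6))
  y <- as.numeric(evaluate_model_batch(X))
  perm <- c(3, 1, 4, 2)
  expect_equal(as.numeric(evaluate_model_batch(X[perm, ])), y[perm])
  # identical rows give a constant vector
  Xc <- X[rep(2, 5), ]
  expect_equal(as.numeric(evaluate_model_batch(Xc)), rep(y[2], 5))
  expect_error(evaluate_model_batch(cbind(nonsense = 1)), "unknown")
})

test_that("invariant-violating rows are flagged, not dropped", {
  X <- cbind(achievable_cell_concentration = c(1e7, 3e8))
  expect_warning(y <- evaluate_model_batch(X), "packing")
  expect_equal(length(y), 2)
  expect_false(is.na(y[1]))
  expect_true(is.na(y[2]))
  expect_identical(attr(y, "violation"), c(FALSE, TRUE))
})

test_that("default bounds are valid and anchored to the baseline", {
  b <- sensitivity_bounds()
  expect_true(all(b$lower < b$upper))
  p <- scenario_preset("scenario1")
  v <- unlist(p[b$parameter])
  expect_true(all(b$lower <= v & v <= b$upper))
  # efficiency-type parameters stay in their valid ranges
  expect_lte(b$upper[b$parameter == "debt_fraction"], 1)
  expect_lte(b$upper[b$parameter == "heat_exchanger_efficiency"], 1)
  # temperature orderings hold for every corner of the box
  expect_lt(b$upper[b$parameter == "media_inlet_temperature"],
            b$lower[b$parameter == "culture_temperature"])
  expect_lt(b$upper[b$parameter == "acbm_chilled_temperature"],
            b$lower[b$parameter == "acbm_outlet_temperature"])
})

test_that("min-max normalization and the DGSM root transform", {
  raw <- cbind(SSA = c(0, 5, 10), DGSM = c(0, 2^16, 2^32))
  rownames(raw) <- c("a", "b", "c")
  norm <- normalize_scores(raw)
  expect_equal(unname(norm[, "SSA"]), c(0, 0.5, 1))
  # sixteenth root first: 0, 2, 4 -> 0, 0.5, 1
  expect_equal(unname(norm[, "DGSM"]), c(0, 0.5, 1))
  expect_true(all(norm >= 0 & norm <= 1))
  # an affine map leaves an already-[0,1] column unchanged
  raw2 <- cbind(MM = c(0, 0.25, 1))
  expect_equal(unname(normalize_scores(raw2)[, 1]), c(0, 0.25, 1))
  # constant columns are defined as zero
  expect_message(normc <- normalize_scores(cbind(MM = c(2, 2, 2))),
                 "constant")
  expect_equal(unname(normc[, 1]), c(0, 0, 0))
  expect_error(normalize_scores(cbind(DGSM = c(-1, 1))), "DGSM")
})

test_that("consensus union respects its combinatorial bounds", {
  mk <- function(...) {
    m <- cbind(...)
    rownames(m) <- paste0("p", seq_len(nrow(m)))
    m
  }
  # full agreement: union size k
  agree <- mk(A = 10:1, B = 10:1)
  expect_identical(consensus_top_k(agree, 3), c("p1", "p2", "p3"))
  # complete disagreement: union size k * algorithms
  disjoint <- mk(A = c(2, 1, 0, 0), B = c(0, 0, 2, 1))
  expect_identical(sort(consensus_top_k(disjoint, 2)),
                   c("p1", "p2", "p3", "p4"))
  # saturation at k = parameter count
  expect_length(consensus_top_k(agree, 10), 10)
  expect_error(consensus_top_k(agree, 11), "between 1")
  # deterministic tie-break by canonical order
  tied <- mk(A = c(1, 1, 1, 0))
  expect_identical(consensus_top_k(tied, 2), c("p1", "p2"))
})

test_that("sobol indices on the Ishigami oracle are close at modest n", {
  bounds <- ishigami_bounds()
  set.seed(11)
  s <- gsa_sobol(ishigami, bounds$lower, bounds$upper, n = 2048)
  expect_lt(max(abs(s - ishigami_s1())), 0.06)
  expect_gt(s[["x2"]], s[["x1"]])
  expect_gt(s[["x1"]], s[["x3"]])
})

test_that("every estimator ranks a dummy parameter last", {
  f <- function(X) 3 * X[, 1] + X[, 2]^2
  lower <- c(x1 = 0, x2 = 0, dummy = 0)
  upper <- c(x1 = 1, x2 = 1, dummy = 1)
  ests <- list(
    function() gsa_sobol(f, lower, upper, n = 256),
    function() gsa_morris(f, lower, upper, r = 20),
    function() gsa_fast(f, lower, upper, n = 257),
    function() gsa_rbdfast(f, lower, upper, n = 512),
    function() gsa_dgsm(f, lower, upper, n = 128),
    function() gsa_dmim(f, lower, upper, n = 512)
  )
  for (i in seq_along(ests)) {
    set.seed(300 + i)
    s <- ests[[i]]()
    expect_lt(s[["dummy"]], min(s[["x1"]], s[["x2"]]), label = i)
    # top-2 of 3 never includes the inert parameter
    expect_false("dummy" %in% names(sort(-s))[1:2])
  }
})

test_that("the six-algorithm run is reproducible under a fixed seed", {
  b <- sensitivity_bounds()
  r1 <- do.call(run_algorithms, c(list(bounds = b, k = 5, seed = 99),
                                  small_sizes))
  r2 <- do.call(run_algorithms, c(list(bounds = b, k = 5, seed = 99),
                                  small_sizes))
  expect_identical(r1$raw, r2$raw)
  expect_identical(r1$consensus, r2$consensus)
  r3 <- do.call(run_algorithms, c(list(bounds = b, k = 5, seed = 100),
                                  small_sizes))
  expect_false(identical(r1$raw, r3$raw))
  # structural invariants of the result
  expect_identical(dim(r1$raw), c(nrow(b), 6L))
  expect_true(all(r1$normalized >= 0 & r1$normalized <= 1))
  expect_gte(length(r1$consensus), 5)
  expect_lte(length(r1$consensus), 30)
  expect_length(consensus_top_k(r1, nrow(b)), nrow(b))
})

test_that("sample-size floors are enforced with the algorithm named", {
  b <- ishigami_bounds()
  expect_error(gsa_sobol(ishigami, b$lower, b$upper, n = 1), "gsa_sobol")
  expect_error(gsa_fast(ishigami, b$lower, b$upper, n = 10), "gsa_fast")
  expect_error(gsa_dmim(ishigami, b$lower, b$upper, n = 10), "gsa_dmim")
})
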