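test_that("DAG construction validates structure", {
  d <- causal_dag("chain", c("A -> B", "B -> C"))
  expect_identical(d$order, c("A", "B", "C"))
  expect_error(causal_dag("cyc", c("A -> B", "B -> A")), "cyclic")
  expect_error(causal_dag("dup", c("A -> B", "A -> B")), "duplicate")
  expect_error(causal_dag("loop", "A -> A"), "self-loops")
})

test_that("basis sets match textbook cases and ignore insertion order", {
  chain <- causal_dag("chain", c("A -> B", "B -> C"))
  bs <- basis_set(chain)
  expect_length(bs, 1)
  expect_identical(bs[[1]]$x, "A")
  expect_identical(bs[[1]]$y, "C")
  expect_identical(bs[[1]]$z, "B")

  full <- causal_dag("sat", c("A -> B", "A -> C", "B -> C"))
  expect_length(basis_set(full), 0)

  collider <- causal_dag("coll", c("A -> C", "B -> C"))
  bc <- basis_set(collider)
  expect_length(bc, 1)
  expect_setequal(c(bc[[1]]$x, bc[[1]]$y), c("A", "B"))
  expect_length(bc[[1]]$z, 0)

  # vertex insertion order does not matter
  chain2 <- causal_dag("chain", c("B -> C", "A -> B"))
  expect_identical(basis_set(chain2), basis_set(chain))
})

test_that("claim tests use the right engine and respond to dependence", {
  n <- 60
  star <- star_tree(n)
  set.seed(1)
  x <- rnorm(n)
  dat <- data.frame(A = x, C = x, B = rnorm(n), row.names = star$tip.label)
  claim <- list(x = "A", y = "C", z = character(0))
  expect_lt(test_claim(claim, dat, star), 1e-6)

  # conditioning on the mediator raises the p-value on chain data
  tr <- simulate_tree(80, seed = 2)
  set.seed(3)
  a <- rnorm(80)
  b <- a + rnorm(80, 0, 0.5)
  c_ <- b + rnorm(80, 0, 0.5)
  dchain <- data.frame(A = a, B = b, C = c_, row.names = tr$tip.label)
  p_marg <- test_claim(list(x = "A", y = "C", z = character(0)), dchain, tr)
  p_cond <- test_claim(list(x = "A", y = "C", z = "B"), dchain, tr)
  expect_gt(p_cond, p_marg)

  expect_error(test_claim(list(x = "A", y = "Z", z = character(0)),
                          dchain, tr), "missing variables")
})

test_that("d-separation p-values are uniform when the claim holds", {
  star <- star_tree(50)
  set.seed(4)
  ps <- replicate(200, {
    d <- data.frame(X = rnorm(50), Y = rnorm(50), Z = rnorm(50),
                    row.names = star$tip.label)
    test_claim(list(x = "X", y = "Y", z = "Z"), d, star)
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Fisher's C follows its closed form and chi-square moments", {
  expect_equal(fisher_c(c(1, 1))$C, 0)
  expect_equal(fisher_c(c(1, 1))$p, 1)
  one <- fisher_c(0.05)
  expect_equal(one$C, -2 * log(0.05), tolerance = 1e-12)
  expect_identical(one$df, 2L)
  expect_warning(out <- fisher_c(c(0.5, 0)), "clamped")
  expect_true(is.finite(out$C))
  sat <- fisher_c(numeric(0))
  expect_equal(sat$C, 0)
  expect_equal(sat$p, 1)

  set.seed(5)
  cs <- replicate(300, fisher_c(runif(20))$C)
  expect_lt(abs(mean(cs) - 40), 3 * sqrt(80 / 300))
})

test_that("CICc evaluates its formula and guards small samples", {
  expect_equal(cicc(0, 0, 10), 0)
  expect_equal(cicc(10, 3, 213), 10 + 6 * 213 / 209, tolerance = 1e-12)
  expect_equal(cicc(4, 2, 1e9), 4 + 4, tolerance = 1e-6)
  expect_error(cicc(1, 5, 6), "n > q")
})

test_that("CICc ranking produces normalized weights and retention flags", {
  single <- rank_and_weight(data.frame(model = "A", CICc = 3))
  expect_equal(single$weight, 1)
  expect_true(single$retained)

  pair <- rank_and_weight(data.frame(model = c("A", "B"), CICc = c(5, 5)))
  expect_equal(pair$weight, c(0.5, 0.5))

  trio <- rank_and_weight(data.frame(model = c("A", "B", "C"),
                                     CICc = c(0, 2, 10)))
  raw <- c(1, exp(-1), exp(-5))
  expect_equal(trio$weight, raw / sum(raw), tolerance = 1e-12)
  expect_identical(trio$retained, c(TRUE, TRUE, FALSE))
  expect_equal(sum(trio$weight), 1, tolerance = 1e-12)
  expect_equal(trio$delta[1], 0)
})

test_that("full-model averaging handles absent edges as zeros", {
  one <- average_paths(
    data.frame(model = "A", from = "x", to = "y", coefficient = 0.7),
    c(A = 1))
  expect_equal(one$coefficient, 0.7)

  two <- average_paths(
    data.frame(model = c("A", "A", "B"),
               from = c("x", "z", "x"), to = c("y", "y", "y"),
               coefficient = c(0.6, 0.8, 0.4)),
    c(A = 0.5, B = 0.5))
  expect_equal(two$coefficient[two$from == "z"], 0.4)   # 0.8 * 0.5 + 0 * 0.5
  expect_equal(two$coefficient[two$from == "x"], 0.5)

  # three overlapping models, hand-computed weighted sums
  tab <- data.frame(
    model = c("A", "A", "B", "B", "C"),
    from = c("s", "t", "s", "l", "t"),
    to = c("t", "l", "l", "t", "l"),
    coefficient = c(0.5, 0.3, 0.2, -0.1, 0.9))
  w <- c(A = 0.6, B = 0.3, C = 0.1)
  avg <- average_paths(tab, w)
  get <- function(f, t) avg$coefficient[avg$from == f & avg$to == t]
  expect_equal(get("s", "t"), 0.6 * 0.5)
  expect_equal(get("t", "l"), 0.6 * 0.3 + 0.1 * 0.9)
  expect_equal(get("s", "l"), 0.3 * 0.2)
  expect_equal(get("l", "t"), 0.3 * (-0.1))

  expect_error(average_paths(tab, numeric(0)), "empty")

  # conditional averaging renormalizes within edge-bearing models
  cond <- average_paths(tab, w, method = "conditional")
  gc <- function(f, t) cond$coefficient[cond$from == f & cond$to == t]
  expect_equal(gc("t", "l"), (0.6 * 0.3 + 0.1 * 0.9) / 0.7)
})

test_that("built-in hypotheses encode the four causal orders", {
  dags <- builtin_hypotheses("ABCD")
  expect_length(dags, 4)
  expect_identical(vapply(dags, `[[`, character(1), "name"),
                   c("A", "B", "C", "D"))
  for (d in dags) {
    expect_identical(nrow(d$edges), 2L)
    expect_length(basis_set(d), 1)
  }
  bsA <- basis_set(dags[[1]])[[1]]
  expect_identical(bsA$x, "sds")
  expect_identical(bsA$y, "length")
  expect_identical(bsA$z, "temp")
  # C and A share a skeleton but orient edges differently
  A <- dags[[1]]; C <- dags[[3]]
  expect_true(any(A$edges$from == "sds" & A$edges$to == "temp"))
  expect_true(any(C$edges$from == "temp" & C$edges$to == "sds"))

  expect_error(builtin_hypotheses("life_history"), "user-configurable")
  lh <- builtin_hypotheses("life_history", topologies = list(
    E = c("sds -> temp", "sds -> lh_index")))
  expect_length(lh, 1)
  expect_error(builtin_hypotheses("life_history",
                                  topologies = list(E = "sds -> foo")),
               "vertices")
})

test_that("the path-model driver ranks hypotheses coherently", {
  tr <- simulate_tree(120, seed = 6)
  set.seed(7)
  dat <- simulate_hypothesis_a(tr)
  res <- suppressWarnings(
    fit_path_models(builtin_hypotheses("ABCD"), dat, tr))
  expect_equal(sum(res$models$weight), 1, tolerance = 1e-12)
  expect_equal(min(res$models$delta), 0)
  expect_true(all(res$models$C >= 0))
  # the generating chain model should be competitive
  expect_true(res$models$retained[res$models$model == "A"])
  # averaged output covers only retained models' edges
  expect_true(all(res$averaged$coefficient |> is.finite()))
  # single retained model: averaging is the identity
  only_a <- suppressWarnings(
    fit_path_models(builtin_hypotheses("ABCD")[1], dat, tr))
  ca <- only_a$coefficients
  expect_equal(only_a$averaged$coefficient,
               ca$coefficient[match(paste(only_a$averaged$from,
                                          only_a$averaged$to),
                                    paste(ca$from, ca$to))])
})
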