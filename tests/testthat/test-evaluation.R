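test_that("hierarchical F1 reproduces the ancestor-set arithmetic", {
  tr <- parseNewick("((B)A)root;")
  ## P = {A}, T = {B, A}: overlap 1 of |P| = 1, |T| = 2
  r <- hierarchicalF1("B", "A", tr)
  expect_equal(r$hP, 1)
  expect_equal(r$hR, 0.5)
  expect_equal(r$HF1, 2 / 3)

  tr2 <- parseNewick("((A,B)1,2)root;")
  r2 <- hierarchicalF1(c("A", "B", "2"), c("A", "B", "2"), tr2)
  expect_equal(r2$HF1, 1)

  ## rejection empties P: precision untouched, recall penalised
  r3 <- hierarchicalF1(c("A", "A"), c("A", "rejected"), tr2)
  expect_equal(r3$hP, 1)
  expect_equal(r3$hR, 0.5)

  expect_error(hierarchicalF1(character(), character(), tr2), "empty")
  expect_error(hierarchicalF1("zzz", "A", tr2), "missing from tree")
})

test_that("hierarchical F1 agrees with a brute-force path-walking oracle", {
  oracle <- function(truth, pred, tree) {
    nd <- tree@nodes
    up <- function(n) {  # walk parent pointers directly on the table
      out <- character()
      while (!is.na(nd$parent[nd$name == n])) {
        out <- c(out, n)
        n <- nd$parent[nd$name == n]
      }
      out
    }
    num <- den.p <- den.t <- 0
    for (i in seq_along(truth)) {
      Ti <- up(truth[[i]])
      Pi <- if (pred[[i]] == "rejected") character() else up(pred[[i]])
      num <- num + length(intersect(Pi, Ti))
      den.p <- den.p + length(Pi)
      den.t <- den.t + length(Ti)
    }
    hP <- if (den.p) num / den.p else 0
    hR <- num / den.t
    list(hP = hP, hR = hR,
         HF1 = if (hP + hR) 2 * hP * hR / (hP + hR) else 0)
  }
  set.seed(99)
  for (case in 1:300) {
    tr <- randomTree(nNodes = sample(2:10, 1L), seed = case)
    pool <- setdiff(nodeNames(tr), "root")
    n <- 30L
    truth <- sample(pool, n, replace = TRUE)
    pred <- sample(c(pool, "rejected"), n, replace = TRUE)
    got <- hierarchicalF1(truth, pred, tr)
    want <- oracle(truth, pred, tr)
    expect_equal(got, want, tolerance = 1e-12)
    ## harmonic-mean bounds
    expect_lte(got$HF1, max(got$hP, got$hR) + 1e-12)
    expect_gte(got$HF1, min(got$hP, got$hR) - 1e-12)
  }
})

test_that("refining an internal prediction to the true leaf never lowers HF1", {
  tr <- parseNewick("((A,B)1,2)root;")
  truth <- c("A", "A", "B", "2")
  internal <- c("1", "1", "1", "2")
  refined <- c("A", "1", "1", "2")
  expect_gte(hierarchicalF1(truth, refined, tr)$HF1,
             hierarchicalF1(truth, internal, tr)$HF1)
})

test_that("median F1 excludes rejected and internal predictions", {
  expect_equal(medianF1(rep(c("a", "b"), each = 5L),
                        rep(c("a", "b"), each = 5L)), 1)

  ## one population perfect, the other fully confused with it:
  ## F1(a) = 2*10/(2*10+10+0) = 2/3, F1(b) = 0 -> median 1/3
  truth <- rep(c("a", "b"), each = 10L)
  pred <- rep("a", 20L)
  expect_equal(medianF1(truth, pred), median(c(2 / 3, 0)))

  ## rejected cells of another population leave a population's F1 alone
  tr <- parseNewick("((A,B)1,2)root;")
  base <- medianF1(c("A", "A"), c("A", "A"), tr)
  with.rej <- medianF1(c("A", "A", "2", "2"),
                       c("A", "A", "rejected", "rejected"), tr)
  expect_equal(base, with.rej)

  ## internal predictions are excluded when a tree is supplied
  expect_equal(medianF1(c("A", "A"), c("A", "1"), tr), 1)
  expect_error(medianF1("A", "rejected", tr), "no cells left")
})

test_that("k-fold evaluation is stratified, deterministic and near-perfect on separable data", {
  d <- makeBlobs(nPer = 45L, seed = 33L, nGenes = 12L,
                 centers = list(c(0, 0), c(10, 0), c(0, 10)),
                 labels = c("a", "b", "c"))
  tr <- flatTree(c("a", "b", "c"))
  r1 <- kfoldEvaluate(d$x, d$labels, tr, kind = "linear", k = 3L,
                      seed = 4L, nComponents = 10L)
  r2 <- kfoldEvaluate(d$x, d$labels, tr, kind = "linear", k = 3L,
                      seed = 4L, nComponents = 10L)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 3L)
  expect_true(all(r1$HF1 > 0.9))
  expect_true(all(r1$pctRejected <= 15))
  expect_error(kfoldEvaluate(d$x, d$labels, tr, k = 60L), "smaller k")
})
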