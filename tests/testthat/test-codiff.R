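test_that("dropout_fraction pools zeros over both conditions", {
  xa <- matrix(c(0, 0, 0, 1, 2, 3, 5, 5, 5), nrow = 3, byrow = TRUE,
               dimnames = list(c("gz", "gmix", "gfull"), paste0("a", 1:3)))
  xb <- matrix(c(0, 0, 0, 0, 0, 0, 0, 4, 4, 4, 1, 1, 1, 1), nrow = 2,
               byrow = TRUE,
               dimnames = list(c("gz", "gfull"), paste0("b", 1:7)))
  # gz present in both: zeros everywhere -> 1
  ca <- expression_matrix(xa); cb <- expression_matrix(xb)
  expect_equal(dropout_fraction(ca, cb, "gz"), 1.0)
  expect_equal(dropout_fraction(ca, cb, "gfull"), 0.0)
  # 3 zeros among 10 cells
  x1 <- matrix(c(0, 0, 0, 1, 1), nrow = 1, dimnames = list("g", paste0("a", 1:5)))
  x2 <- matrix(rep(1, 5), nrow = 1, dimnames = list("g", paste0("b", 1:5)))
  expect_equal(dropout_fraction(expression_matrix(x1), expression_matrix(x2), "g"),
               0.3)
  expect_error(dropout_fraction(ca, cb, "nope"), "absent")
})

test_that("filter_genes_by_dropout retains genes at or below the threshold", {
  # fractions over 10 pooled cells: 0.2, 0.91 is impossible at 10 cells, use 1.0, 0.5
  mk <- function(zeros, tag) {
    v <- c(rep(0, zeros), rep(2, 10 - zeros))
    matrix(v, nrow = 1, dimnames = list("g", paste0(tag, 1:10)))
  }
  ca <- expression_matrix(rbind(g1 = c(0, 0, 2, 2, 2), g2 = c(0, 0, 0, 0, 0),
                                g3 = c(0, 0, 0, 2, 2)))
  colnames(ca$counts) <- paste0("a", 1:5)
  cb <- expression_matrix(rbind(g1 = c(2, 2, 2, 2, 2), g2 = c(0, 0, 0, 0, 2),
                                g3 = c(0, 0, 2, 2, 2)))
  colnames(cb$counts) <- paste0("b", 1:5)
  # fractions: g1 0.2, g2 0.9, g3 0.5
  out <- filter_genes_by_dropout(ca, cb, max_dropout = 0.8)
  expect_equal(rownames(out$case$counts), c("g1", "g3"))
  expect_equal(rownames(out$control$counts), c("g1", "g3"))
  # identity at max_dropout 1
  out1 <- filter_genes_by_dropout(ca, cb, 1)
  expect_equal(nrow(out1$case$counts), 3)
  # boundary: only no-zero genes at max_dropout 0
  out0 <- filter_genes_by_dropout(ca, cb, 0)
  expect_equal(nrow(out0$case$counts), 0)
  # gene of interest protection
  expect_error(filter_genes_by_dropout(ca, cb, 0.8, genes_of_interest = "g2"),
               "g2.*dropout")
})

test_that("compute_codiff subtracts position-wise and validates inputs", {
  ca <- expression_matrix(matrix(c(2, 3), 1, dimnames = list("g", c("a1", "a2"))),
                          normalized = TRUE)
  cb <- expression_matrix(matrix(c(1, 1), 1, dimnames = list("g", c("b1", "b2"))),
                          normalized = TRUE)
  X <- compute_codiff(ca, cb)
  expect_equal(unname(X$X["g", ]), c(1, 2))
  # identical conditions -> zero matrix
  X0 <- compute_codiff(ca, ca)
  expect_true(all(X0$X == 0))
  # unequal cell counts -> instructive error
  cbig <- expression_matrix(matrix(1, 1, 447,
                                   dimnames = list("g", paste0("c", 1:447))))
  csmall <- expression_matrix(matrix(1, 1, 97,
                                     dimnames = list("g", paste0("d", 1:97))))
  expect_error(compute_codiff(csmall, cbig), "subsample")
  # unequal gene sets -> error
  cg <- expression_matrix(matrix(1, 1, 2, dimnames = list("other", c("x", "y"))))
  expect_error(compute_codiff(ca, cg), "gene sets")
})

test_that("compute_codiff is antisymmetric under condition swap", {
  set.seed(4)
  ca <- expression_matrix(matrix(runif(20), 4, 5,
                                 dimnames = list(paste0("g", 1:4), paste0("a", 1:5))))
  cb <- expression_matrix(matrix(runif(20), 4, 5,
                                 dimnames = list(paste0("g", 1:4), paste0("b", 1:5))))
  expect_equal(compute_codiff(ca, cb)$X, -compute_codiff(cb, ca)$X)
})

test_that("select_candidates ranks by absolute correlation with stable ties", {
  t_len <- 50
  set.seed(8)
  base <- rnorm(t_len)
  X <- rbind(goi = base,
             pos = 0.9 * base + 0.1 * rnorm(t_len),
             neg = -base + 0.05 * rnorm(t_len),
             weak = rnorm(t_len),
             flat = rep(1, t_len),
             twin = base)
  cd <- codiff_matrix(X)
  cs <- select_candidates(cd, "goi", k = 3)
  # an exact copy of the goi series has r = 1 and ranks first
  expect_equal(cs$candidates$gene[1], "twin")
  expect_equal(cs$candidates$r[1], 1)
  # anti-correlated regulators are screened in by |r|
  expect_true("neg" %in% cs$candidates$gene)
  # zero-variance genes never appear
  expect_false("flat" %in% cs$candidates$gene)
  # saturation: k >= N-1 returns all finite-variance genes
  all_c <- select_candidates(cd, "goi", k = 10)
  expect_setequal(all_c$candidates$gene, c("twin", "pos", "neg", "weak"))
  # invariant to common positive rescaling of rows
  cs2 <- select_candidates(codiff_matrix(X * 3.7), "goi", k = 3)
  expect_equal(cs2$candidates$gene, cs$candidates$gene)
  # zero-variance goi errors
  expect_error(select_candidates(cd, "flat", k = 2), "no co-differential")
})

test_that("absolute-value ranking oracle on constructed correlations", {
  # construct three series with known correlations to the goi
  t_len <- 400
  set.seed(12)
  z <- rnorm(t_len)
  mk <- function(r) r * z + sqrt(1 - r^2) * rnorm(t_len)
  X <- rbind(goi = z, a = mk(0.9), b = mk(-0.95), c = mk(0.1))
  cs <- select_candidates(codiff_matrix(X), "goi", k = 2)
  # oracle: rank by |sample correlation|
  rs <- sapply(c(a = "a", b = "b", c = "c"), function(g) cor(X[g, ], z))
  expected <- names(sort(-abs(rs)))[1:2]
  expect_equal(cs$candidates$gene, expected)
})

test_that("regulation_sign follows the correlation of the two series", {
  expect_equal(regulation_sign(c(1, 2, 3), c(2, 4, 6)), "positive")
  expect_equal(regulation_sign(c(1, 2, 3), c(3, 2, 1)), "negative")
  # hand-computed r = +0.5
  expect_equal(cor(c(1, 2, 3), c(5, 3, 7)), 0.5)
  expect_equal(regulation_sign(c(1, 2, 3), c(5, 3, 7)), "positive")
  expect_error(regulation_sign(c(1, 1, 1), c(1, 2, 3)), "variance")
  # invariant under joint negation (case/control flip)
  set.seed(3)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20, sd = 0.4)
  expect_equal(regulation_sign(x, y), regulation_sign(-x, -y))
})
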