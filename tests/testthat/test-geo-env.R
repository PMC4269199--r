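coords_df <- function(lat, lon, sites = NULL) {
  data.frame(site = sites %||% paste0("p", seq_along(lat)),
             latitude = lat, longitude = lon)
}

test_that("great-circle matrix has metric structure and known values", {
  expect_equal(great_circle_matrix(coords_df(c(10, 10), c(20, 20)))[1, 2], 0)
  # antipodal points are half a circumference apart
  anti <- great_circle_matrix(coords_df(c(0, 0), c(0, 180)))
  expect_equal(anti[1, 2], pi * 6371, tolerance = 1e-6)
  # symmetry, zero diagonal, triangle inequality on random triples
  set.seed(4)
  for (i in 1:20) {
    g <- great_circle_matrix(coords_df(runif(3, -90, 90), runif(3, -180, 180)))
    expect_equal(g, t(g))
    expect_equal(unname(diag(g)), rep(0, 3))
    expect_lte(g[1, 3], g[1, 2] + g[2, 3] + 1e-9)
  }
})

test_that("neighbouring boreholes from the site table are 4 km apart", {
  t3 <- load_fixture("table3_subsurface")
  g <- great_circle_matrix(t3)
  expect_equal(round(g["Dr5IPC", "TT109"]), 4)
})

test_that("variable scaling z-scores columns and rejects degenerate input", {
  env <- data.frame(site = c("a", "b", "c"), x = c(1, 2, 3), k = c(5, 5, 5))
  s <- scale_variables(env, "x")
  expect_equal(unname(s[, "x"]), c(-1, 0, 1))
  expect_error(scale_variables(env, "k"), "zero-variance")
  expect_error(scale_variables(env, "missing_col"), "not found")
  env$x[2] <- NA
  expect_error(scale_variables(env, "x"), "site.*b|b.*")
  # idempotence: an already-standardised column is unchanged
  env2 <- data.frame(z = c(-1, 0, 1))
  expect_equal(unname(scale_variables(env2, "z")[, 1]), c(-1, 0, 1),
               tolerance = 1e-12)
})

test_that("Euclidean environmental distances match sum-of-squares oracle", {
  m <- rbind(c(0, 0), c(3, 4), c(1, 1), c(-2, 5))
  d <- euclidean_env_distance(m)
  expect_equal(d[1, 2], 5)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d[i, j], sqrt(sum((m[i, ] - m[j, ])^2)))
  expect_error(euclidean_env_distance(rbind(c(1, NA))), "missing")
})

test_that("matrix correlation uses the upper triangle", {
  set.seed(6)
  m1 <- as.matrix(dist(rnorm(5)))
  expect_equal(matrix_correlation(m1, 2 * m1)$pcc, 1)
  expect_equal(matrix_correlation(m1, max(m1) - m1 + 0.01)$pcc, -1)
  m2 <- as.matrix(dist(rnorm(5)))
  mc <- matrix_correlation(m1, m2)
  expect_equal(mc$pcc, cor(m1[upper.tri(m1)], m2[upper.tri(m2)]))
  expect_equal(mc$r2, mc$pcc^2)
  expect_error(matrix_correlation(m1, matrix(1, 5, 5)), "constant")
  # full-matrix compatibility mode vectorises everything
  mcf <- matrix_correlation(m1, m2, mode = "full")
  expect_equal(mcf$pcc, cor(as.vector(m1), as.vector(m2)))
})

test_that("bioenv enumerates all nonempty subsets and ranks them", {
  set.seed(8)
  env <- data.frame(site = paste0("s", 1:6),
                    matrix(rnorm(6 * 9), 6, dimnames = list(NULL, paste0("v", 1:9))))
  dm <- as.matrix(dist(rnorm(6))); rownames(dm) <- colnames(dm) <- env$site
  b <- bioenv(env, paste0("v", 1:9), dm)
  expect_equal(b$n_subsets, 511)
  expect_equal(b$best_pcc, max(b$ranking$pcc))
  # best over all subsets dominates the full-variable subset
  full <- b$ranking[b$ranking$size == 9, ]
  expect_gte(b$best_pcc, full$pcc)
  b1 <- bioenv(env, "v1", dm)
  expect_equal(b1$n_subsets, 1)
  expect_equal(b1$best_subset, "v1")
  expect_error(bioenv(env, paste0("v", 1:9), dm, max_vars = 5), "guard")
})

test_that("bioenv agrees with an independent naive re-implementation (k <= 4)", {
  set.seed(10)
  env <- data.frame(site = paste0("s", 1:7),
                    matrix(rnorm(7 * 4), 7, dimnames = list(NULL, paste0("v", 1:4))))
  dm <- as.matrix(dist(rnorm(7))); rownames(dm) <- colnames(dm) <- env$site
  b <- bioenv(env, paste0("v", 1:4), dm)
  # naive: explicit z-scores, explicit pairwise distances, explicit Pearson
  naive_best <- -Inf; naive_subset <- NULL
  vars <- paste0("v", 1:4)
  for (mask in 1:15) {
    vs <- vars[as.logical(bitwAnd(mask, 2^(0:3)))]
    z <- sapply(vs, function(v) (env[[v]] - mean(env[[v]])) / sd(env[[v]]))
    z <- matrix(z, nrow = 7)
    ed <- matrix(0, 7, 7)
    for (i in 1:7) for (j in 1:7) ed[i, j] <- sqrt(sum((z[i, ] - z[j, ])^2))
    x <- ed[upper.tri(ed)]; y <- dm[upper.tri(dm)]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    if (r > naive_best) { naive_best <- r; naive_subset <- vs }
  }
  expect_equal(b$best_pcc, naive_best)
  expect_setequal(b$best_subset, naive_subset)
})

test_that("bioenv agrees with the vegan implementation on the best subset", {
  skip_if_not_installed("vegan")
  set.seed(13)
  env <- data.frame(matrix(rnorm(7 * 5), 7,
                           dimnames = list(NULL, paste0("v", 1:5))))
  comm_d <- as.matrix(dist(rnorm(7)))
  rownames(comm_d) <- colnames(comm_d) <- rownames(env) <- paste0("s", 1:7)
  ours <- bioenv(env, paste0("v", 1:5), comm_d)
  ref <- vegan::bioenv(as.dist(comm_d), env, index = "euclidean",
                       method = "pearson")
  best_ref <- names(ref$models[[which.max(sapply(ref$models, `[[`,
                                                 "est"))]]$best)
  ref_vars <- colnames(env)[ref$models[[which.max(
    sapply(ref$models, `[[`, "est"))]]$best]
  expect_setequal(ours$best_subset, ref_vars)
  expect_equal(ours$best_pcc, max(sapply(ref$models, `[[`, "est")),
               tolerance = 1e-10)
})

test_that("planted environmental drivers are recovered", {
  sub <- generate_community(community_scenario("subsurface"), seed = 7)
  dm <- dissimilarity_matrix(sub)
  vars <- paste0("v", 1:8)
  env <- generate_env(dm, vars, planted = c("v1", "v2"), noise_sd = 0.2,
                      seed = 1)
  b <- bioenv(env, vars, dm)
  expect_true(all(c("v1", "v2") %in% b$best_subset))
  # one perfect driver of a line-structured community recovers R2 ~ 1
  line_d <- as.matrix(dist(1:6))
  rownames(line_d) <- colnames(line_d) <- paste0("s", 1:6)
  env1 <- generate_env(line_d, c("v1", "v2", "v3"), planted = "v1",
                       noise_sd = 0, seed = 2)
  b1 <- bioenv(env1, c("v1", "v2", "v3"), line_d)
  expect_equal(b1$best_subset, "v1")
  expect_gte(b1$best_r2, 0.95)
})

test_that("depth estimation reproduces published bounds and is linear", {
  d <- estimate_depth(58)
  expect_equal(d$depth_min_m, 1267)
  expect_equal(d$depth_max_m, 1900)
  d2 <- estimate_depth(c(63, 67))   # midpoint 65
  expect_equal(d2$depth_max_m, 2250)
  expect_equal(estimate_depth(20)$depth_min_m, 0)
  expect_error(estimate_depth(15), "below surface")
  # linear in the temperature excess (up to nearest-metre rounding)
  a <- estimate_depth(30); b <- estimate_depth(40)
  expect_equal(b$depth_max_m, 2 * a$depth_max_m)
  expect_lte(abs(b$depth_min_m - 2 * a$depth_min_m), 1)
})
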