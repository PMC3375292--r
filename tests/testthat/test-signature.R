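make_vce <- function(...) {
  # build a vce object from (component, factor, variance) triplets
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(component = r[[1]], factor = r[[2]],
               variance = as.numeric(r[[3]]), truncated = FALSE)))
  class(df) <- c("vce", "data.frame")
  df
}

test_that("signature information follows the closed forms", {
  v <- make_vce(list("PC1", "individual", 3), list("PC1", "residual", 1))
  si <- signature_information(v, "individual")
  expect_equal(si$per_component$H_i, 1)              # log2(sqrt(4)/sqrt(1))
  expect_equal(si$per_component$repeatability, 0.75)
  v0 <- make_vce(list("PC1", "individual", 0), list("PC1", "residual", 2))
  si0 <- signature_information(v0, "individual")
  expect_equal(si0$H_s_bits, 0)
  expect_equal(si0$per_component$repeatability, 0)
  v3 <- make_vce(list("PC1", "individual", 1), list("PC1", "residual", 1),
                 list("PC2", "individual", 2), list("PC2", "residual", 2),
                 list("PC3", "individual", 5), list("PC3", "residual", 5))
  expect_equal(signature_information(v3, "individual")$H_s_bits, 1.5)
  vz <- make_vce(list("PC1", "individual", 1), list("PC1", "residual", 0))
  expect_error(signature_information(vz, "individual"), "infinite")
})

test_that("H_i and repeatability are scale invariant and monotone in S_B2", {
  for (c2 in c(0.1, 1, 25)) {
    v <- make_vce(list("PC1", "individual", 3 * c2),
                  list("PC1", "residual", 1 * c2))
    si <- signature_information(v, "individual")
    expect_equal(si$per_component$H_i, 1)
    expect_equal(si$per_component$repeatability, 0.75)
  }
  h <- vapply(c(0.5, 1, 2, 4), function(sb) {
    v <- make_vce(list("PC1", "individual", sb), list("PC1", "residual", 1))
    signature_information(v, "individual")$H_s_bits
  }, numeric(1))
  expect_true(all(diff(h) > 0))
})

test_that("signature variance sums the declared factors only", {
  v <- make_vce(list("PC1", "species", 4), list("PC1", "colony", 1),
                list("PC1", "individual", 2), list("PC1", "residual", 1))
  si <- signature_information(v, c("colony", "individual"))
  expect_equal(si$per_component$S_B2, 3)
  expect_equal(si$per_component$S_T2, 4)   # species variance excluded
  expect_equal(si$H_s_bits, 1)
})

test_that("weighted variance attribution sums to 100 with sane cases", {
  m <- list(loadings = matrix(0.5, 2, 1, dimnames = list(NULL, "PC1")),
            varprop = c(PC1 = 0.4))
  class(m) <- "pc_model"
  v <- make_vce(list("PC1", "individual", 1), list("PC1", "residual", 1))
  a <- weighted_variance_attribution(v, m)
  expect_equal(unname(a["individual"]), 50)
  expect_equal(sum(a), 100)
  v0 <- make_vce(list("PC1", "individual", 0), list("PC1", "residual", 1))
  expect_equal(unname(weighted_variance_attribution(v0, m)["residual"]), 100)
  # two components with different weights
  m2 <- list(loadings = matrix(0.5, 2, 2,
                               dimnames = list(NULL, c("PC1", "PC2"))),
             varprop = c(PC1 = 0.5, PC2 = 0.25))
  class(m2) <- "pc_model"
  v2 <- make_vce(list("PC1", "individual", 1), list("PC1", "residual", 1),
                 list("PC2", "individual", 0), list("PC2", "residual", 1))
  a2 <- weighted_variance_attribution(v2, m2)
  expect_equal(unname(a2["individual"]), 100 * (0.5 * 0.5) / 0.75)
  expect_equal(sum(a2), 100, tolerance = 1e-6)
})
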