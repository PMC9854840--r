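unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

test_that("centroid size follows its definition and similarity behaviour", {
  expect_equal(centroid_size(unit_square), sqrt(2))
  expect_equal(centroid_size(unit_square * 3.7), 3.7 * sqrt(2))
  shifted <- sweep(unit_square, 2L, c(5, -3), `+`)
  expect_equal(centroid_size(shifted), sqrt(2))
  expect_error(centroid_size(matrix(1, 4L, 2L)), "coincide")
  expect_error(centroid_size(unit_square[1L, , drop = FALSE]),
               "at least 2")
})

test_that("GPA removes similarity transforms exactly", {
  tri <- rbind(c(0, 0), c(4, 0), c(1, 3))
  th <- pi / 2
  R <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  tri2 <- sweep(3 * (tri %*% R), 2L, c(10, -7), `+`)
  al <- gpa(list(list(id = "a", coords = tri), list(id = "b", coords = tri2)))
  expect_lt(sqrt(sum((al$shapes[1L, ] - al$shapes[2L, ])^2)), 1e-10)
  expect_equal(al$centroid_sizes[2L] / al$centroid_sizes[1L], 3)
})

test_that("GPA output is invariant to per-specimen similarity transforms", {
  cfgs <- random_configs(8L, seed = 9L)
  al0 <- gpa(cfgs)
  set.seed(10)
  jittered <- lapply(cfgs, function(cf) {
    th <- runif(1, 0, 2 * pi)
    R <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    cf$coords <- sweep(runif(1, 0.5, 4) * (cf$coords %*% R), 2L,
                       runif(2, -9, 9), `+`)
    cf
  })
  al1 <- gpa(jittered)
  # compare after aligning the two consensus orientations
  r0 <- morphherit:::unflatten_(al0$consensus)
  r1 <- morphherit:::unflatten_(al1$consensus)
  R <- morphherit:::rot_fit_(r1, r0)
  for (i in seq_along(cfgs)) {
    s0 <- morphherit:::unflatten_(al0$shapes[i, ])
    s1 <- morphherit:::unflatten_(al1$shapes[i, ]) %*% R
    expect_lt(max(abs(s0 - s1)), 1e-8)
  }
})

test_that("aligned shapes are centred with unit centroid size and the
           consensus is their mean", {
  al <- gpa(random_configs(12L, seed = 3L))
  arr <- morphherit:::shapes_array_(al)
  for (i in seq_len(dim(arr)[3L])) {
    expect_lt(max(abs(colMeans(arr[, , i]))), 1e-10)
    expect_lt(abs(sqrt(sum(arr[, , i]^2)) - 1), 1e-10)
  }
  # consensus in the output is the normalized mean direction of the shapes
  cons_hat <- colMeans(al$shapes)
  cons_hat <- cons_hat / sqrt(sum(cons_hat^2))
  expect_lt(max(abs(cons_hat - al$consensus)), 1e-8)
})

test_that("Procrustes residual sum of squares is non-increasing across
           iterations", {
  al <- gpa(random_configs(15L, seed = 21L, noise = 0.03))
  rss <- attr(al, "rss")
  expect_gt(length(rss), 1L)
  expect_true(all(diff(rss) <= 1e-12))
})

test_that("GPA matches a grid-search rotation oracle on three triangles", {
  tris <- list(rbind(c(0, 0), c(4, 0), c(1, 3)),
               rbind(c(0.2, -0.1), c(3.7, 0.4), c(0.8, 2.9)),
               rbind(c(-0.3, 0.1), c(4.2, -0.2), c(1.4, 3.3)))
  al <- gpa(lapply(seq_along(tris), function(i)
    list(id = as.character(i), coords = tris[[i]])))
  or <- oracle_gpa(tris)
  # align the oracle solution globally onto ours, then compare
  R <- morphherit:::rot_fit_(or$consensus,
                             morphherit:::unflatten_(al$consensus))
  for (i in seq_along(tris)) {
    ours <- morphherit:::unflatten_(al$shapes[i, ])
    expect_lt(max(abs(or$shapes[[i]] %*% R - ours)), 1e-6)
  }
  orc <- or$consensus / sqrt(sum(or$consensus^2))  # ours is unit-size
  expect_lt(max(abs(orc %*% R -
                      morphherit:::unflatten_(al$consensus))), 1e-6)
})

test_that("semilandmark sliding reduces bending energy and is a no-op at
           the fixed point", {
  sch <- viper_head_scheme()
  cfgs <- random_configs(20L, seed = 5L, noise = 0.004)
  plain <- gpa(cfgs, sch, slide = FALSE)
  slid <- gpa(cfgs, sch, slide = TRUE)
  be <- morphherit:::bending_energy_matrix_(
    morphherit:::unflatten_(slid$consensus))
  total_be <- function(al) {
    cons <- morphherit:::unflatten_(al$consensus)
    arr <- morphherit:::shapes_array_(al)
    sum(vapply(seq_len(dim(arr)[3L]), function(i) {
      v <- arr[, , i] - cons
      drop(t(v[, 1L]) %*% be %*% v[, 1L] + t(v[, 2L]) %*% be %*% v[, 2L])
    }, 0))
  }
  expect_lt(total_be(slid), total_be(plain))

  # when every specimen already sits at the consensus, the bending-energy
  # gradient vanishes and sliding is a no-op: slide = TRUE equals
  # slide = FALSE
  tm <- viper_head_template()
  same <- lapply(1:4, function(i) {
    th <- i / 3
    Rm <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    list(id = as.character(i), coords = (2 + i) * tm %*% Rm)
  })
  a_fix <- gpa(same, sch, slide = FALSE)
  a_slide <- gpa(same, sch, slide = TRUE)
  expect_lt(max(abs(a_fix$shapes - a_slide$shapes)), 1e-8)
})

test_that("tangent projection places shapes in the hyperplane at the
           consensus", {
  al <- gpa(random_configs(10L, seed = 13L), proj = TRUE)
  cu <- al$consensus / sqrt(sum(al$consensus^2))
  expect_lt(max(abs(al$shapes %*% cu - sqrt(sum(al$consensus^2)))), 1e-10)
})

test_that("gpa rejects degenerate input", {
  expect_error(gpa(list(list(id = "a", coords = unit_square))),
               "at least 2")
  degen <- list(list(id = "a", coords = matrix(2, 4L, 2L)),
                list(id = "b", coords = unit_square))
  expect_error(gpa(degen), "coincide")
})
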