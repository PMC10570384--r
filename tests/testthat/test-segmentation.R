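test_that("slab averaging matches a brute-force oracle for all small schemes", {
  set.seed(5)
  for (nz in c(7, 12, 20)) {
    stack <- array(rnorm(10 * 11 * nz), c(10, 11, nz))
    for (gs in 1:4) {
      for (sk in 0:3) {
        if (nz < gs) next
        got <- slab_average(stack, slab_scheme(gs, sk, z_step = 3))
        ref <- slab_oracle(stack, gs, sk, z_step = 3)
        expect_equal(dim(got$slabs)[3], length(ref$slabs))
        for (k in seq_along(ref$slabs))
          expect_equal(got$slabs[, , k], ref$slabs[[k]], tolerance = 1e-12)
        expect_equal(got$depth, ref$depth)
      }
    }
  }
})

test_that("slab counts follow the start-period-drop policy", {
  big <- array(0, c(2, 2, 100))
  expect_equal(dim(slab_average(big, slab_scheme())$slabs)[3], 20)

  three <- array(seq_len(2 * 2 * 3), c(2, 2, 3))
  got <- slab_average(three, slab_scheme())
  expect_equal(dim(got$slabs)[3], 1)
  expect_equal(got$slabs[, , 1],
               (three[, , 1] + three[, , 2] + three[, , 3]) / 3)

  four <- array(seq_len(2 * 2 * 4), c(2, 2, 4))
  got4 <- slab_average(four, slab_scheme())
  expect_equal(dim(got4$slabs)[3], 1)  # slice 4 dropped, not averaged alone

  expect_error(slab_average(array(0, c(2, 2, 2)), slab_scheme()),
               "group_size")
})

test_that("builtin segmentation labels disjoint bright disks", {
  img <- matrix(0, 120, 120)
  centers <- expand.grid(r = c(20, 60, 100), c = c(20, 60, 100))
  centers <- rbind(centers, data.frame(r = 40, c = 110))  # 10th disk
  for (k in seq_len(nrow(centers))) {
    rr <- outer(seq_len(120), rep(1, 120)) - centers$r[k]
    cc <- outer(rep(1, 120), seq_len(120)) - centers$c[k]
    img[rr^2 + cc^2 <= 36] <- 100
  }
  lab <- segment_cells(img, min_area = 10, threshold_quantile = 0.2,
                       smooth_sigma = 1)
  expect_equal(max(lab), 10)

  blank <- segment_cells(matrix(0, 30, 30))
  expect_equal(max(blank), 0)
})

test_that("builtin segmentation is deterministic and 8-connected", {
  set.seed(8)
  img <- matrix(runif(900), 30, 30)
  expect_identical(segment_cells(img), segment_cells(img))

  # two blobs touching only diagonally form one component
  diagimg <- matrix(0, 12, 12)
  diagimg[3:5, 3:5] <- 10
  diagimg[6:8, 6:8] <- 10
  lab <- segment_cells(diagimg, min_area = 1, threshold_quantile = 0,
                       smooth_sigma = 0)
  expect_equal(max(lab), 1)
})

test_that("builtin mask agrees with ground truth at the count level", {
  built <- 0; truth_total <- 0
  for (seed in 4:7) {
    sc <- make_scene(n_cells = 20, dim = c(160L, 160L, 8L), seed = seed)
    post <- render_scene(sc, optical_model(), pc_model(), dose = 300,
                         seed = seed + 10)
    for (k in seq_len(dim(post$green)[3])) {
      m <- post$mask[, , k]
      truth_n <- sum(table(m[m > 0]) >= 10)  # cells with a usable section
      img <- post$green[, , k] + post$red[, , k]
      img <- pmax(img - (median(img) + 5 * mad(img)), 0)
      lab <- segment_cells(img, min_area = 10)
      built <- built + max(lab)
      truth_total <- truth_total + truth_n
    }
  }
  agreement <- min(built, truth_total) / max(built, truth_total)
  expect_gte(agreement, 0.95)
})

test_that("extraction reports exact means, areas, and honours min_area", {
  mask <- matrix(0L, 10, 10)
  mask[2:4, 2:4] <- 1L
  mask[8, 8] <- 2L
  green <- matrix(100, 10, 10)
  red <- matrix(17, 10, 10)
  tbl <- extract_cell_fluorescence(mask, green, red, depth = 12)
  expect_equal(tbl$mean_green, c(100, 100))
  expect_equal(tbl$mean_red, c(17, 17))
  expect_equal(tbl$pixel_count, c(9L, 1L))
  expect_equal(tbl$depth, c(12, 12))

  small <- extract_cell_fluorescence(mask, green, red, min_area = 2)
  expect_identical(small$cell_id, 1L)

  expect_error(extract_cell_fluorescence(mask, green[1:5, ], red),
               "dimensions differ")
  expect_warning(extract_cell_fluorescence(mask, green, red,
                                           expected_ids = c(1L, 2L, 9L)),
                 "absent")
})

test_that("extraction is invariant under label permutation", {
  set.seed(6)
  mask <- matrix(sample(0:4, 400, replace = TRUE), 20, 20)
  green <- matrix(rnorm(400, 100), 20, 20)
  red <- matrix(rnorm(400, 30), 20, 20)
  tbl <- extract_cell_fluorescence(mask, green, red)
  perm <- c(3L, 1L, 4L, 2L)  # relabel i -> perm[i]
  pmask <- mask
  pmask[mask > 0] <- perm[mask[mask > 0]]
  ptbl <- extract_cell_fluorescence(pmask, green, red)
  reord <- match(perm[tbl$cell_id], ptbl$cell_id)
  expect_equal(ptbl$mean_green[reord], tbl$mean_green)
  expect_equal(ptbl$mean_red[reord], tbl$mean_red)
  expect_equal(ptbl$pixel_count[reord], tbl$pixel_count)
})

test_that("pre/post matching pairs identical masks and rejects far shifts", {
  sc <- tiny_scene(n_cells = 10, seed = 19)
  st <- render_scene(sc, noiseless_optical(), pc_model(), phase = "pre")
  m <- st$mask
  pairs <- match_cells_pre_post(m, m, max_dist = 1,
                                pixel_size = sc$pixel_size,
                                z_step = sc$z_step)
  expect_equal(nrow(pairs), 10)
  expect_identical(pairs$id_pre, pairs$id_post)
  expect_length(attr(pairs, "unmatched_pre"), 0)

  shifted <- array(0L, dim(m))
  shifted[, 1:(dim(m)[2] - 60), ] <- m[, 61:dim(m)[2], ]
  far <- match_cells_pre_post(m, shifted, max_dist = 5,
                              pixel_size = sc$pixel_size,
                              z_step = sc$z_step)
  expect_equal(nrow(far), 0)
})

test_that("matching survives sub-cap centroid jitter", {
  set.seed(23)
  correct <- 0; total <- 0
  for (rep in 1:5) {
    sc <- tiny_scene(n_cells = 12, seed = 300 + rep)
    st <- render_scene(sc, noiseless_optical(), pc_model(), phase = "pre")
    jit <- sc
    jit$cells$x <- jit$cells$x + runif(12, -1, 1)
    jit$cells$y <- jit$cells$y + runif(12, -1, 1)
    jt <- try(render_scene(jit, noiseless_optical(), pc_model(),
                           phase = "pre"), silent = TRUE)
    if (inherits(jt, "try-error")) next  # jitter created an overlap
    pairs <- match_cells_pre_post(st$mask, jt$mask, max_dist = 4,
                                  pixel_size = sc$pixel_size,
                                  z_step = sc$z_step)
    correct <- correct + sum(pairs$id_pre == pairs$id_post)
    total <- total + nrow(pairs)
  }
  expect_gte(correct / total, 0.99)
})
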