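test_that("uniform resting tissue stays uniform and follows the 0D trajectory", {
  g <- tissue_geometry(20, 20, 0.02, 1.3e-3)
  init <- cell_model("courtemanche")$init_state
  rec <- run_tissue("courtemanche", geometry = g, init = init,
                    duration = 100, frame_dt = 0)
  v <- rec$final_state[1, ]
  expect_lt(max(v) - min(v), 1e-9)
  # zero-coupling reference: the same cells with D = 0 (pure reaction)
  g0 <- tissue_geometry(3, 3, 0.02, 0)
  ref <- run_tissue("courtemanche", geometry = g0, init = init,
                    duration = 100, frame_dt = 0)
  expect_lt(max(abs(v - ref$final_state[1, 1])), 1e-6)
})

test_that("D = 0 decouples nodes: a perturbed node never touches its neighbors", {
  surrogate_model(140)
  g <- tissue_geometry(5, 5, 0.05, 0)
  ns <- cell_model("surrogate")$n_state
  y0 <- matrix(cell_model("surrogate")$init_state, ns, 25)
  y0[1, 13] <- y0[1, 13] + 60  # excite the center node only
  rec <- run_tissue("surrogate", geometry = g, init = y0, duration = 50,
                    frame_dt = 0)
  ref <- run_tissue("surrogate", geometry = g,
                    init = matrix(cell_model("surrogate")$init_state, ns, 25),
                    duration = 50, frame_dt = 0)
  off <- setdiff(1:25, 13)
  expect_identical(rec$final_state[, off], ref$final_state[, off])
  expect_gt(abs(rec$final_state[1, 13] - ref$final_state[1, 13]), 1e-6)
})

test_that("the discrete no-flux Laplacian conserves total voltage (dense-matrix oracle)", {
  # with INa and IKr scalings both zero the surrogate reaction leaves V
  # untouched, so the kernel advances V by pure diffusion
  nx <- 7; ny <- 6; nn <- nx * ny
  dx <- 0.05; D <- 1e-3; dt <- 0.02
  g <- tissue_geometry(nx, ny, dx, D)
  ns <- cell_model("surrogate")$n_state
  v0 <- sin(seq_len(nn)) * 20 - 60
  y0 <- rbind(v0, matrix(1, ns - 1, nn))
  frozen <- scaling(INa = 0, IKr = 0)
  rec <- run_tissue("surrogate", frozen, g, init = y0, duration = dt,
                    frame_dt = 0, dt = dt)
  # dense mirror-boundary Laplacian
  L <- matrix(0, nn, nn)
  idx <- function(ix, iy) (ix - 1) * ny + iy
  for (ix in 1:nx) for (iy in 1:ny) {
    n <- idx(ix, iy)
    nbr <- c(idx(ifelse(ix == 1, 2, ix - 1), iy),
             idx(ifelse(ix == nx, nx - 1, ix + 1), iy),
             idx(ix, ifelse(iy == 1, 2, iy - 1)),
             idx(ix, ifelse(iy == ny, ny - 1, iy + 1)))
    for (m in nbr) L[n, m] <- L[n, m] + 1
    L[n, n] <- L[n, n] - 4
  }
  expect_equal(rowSums(L), rep(0, nn))  # null row sums: uniform fields are fixed
  v1 <- v0 + D * dt / dx^2 * as.numeric(L %*% v0)
  expect_equal(rec$final_state[1, ], v1, tolerance = 1e-12)
  # multi-step equivalence: the kernel iterates the same dense update
  rec2 <- run_tissue("surrogate", frozen, g, init = y0, duration = 50,
                     frame_dt = 0, dt = dt)
  v <- v0
  for (i in seq_len(round(50 / dt))) v <- v + D * dt / dx^2 * as.numeric(L %*% v)
  expect_equal(rec2$final_state[1, ], v, tolerance = 1e-8)
})

test_that("a planar wave leaves no boundary reflection (each node activates exactly once)", {
  surrogate_model(140)
  g <- tissue_geometry(80, 10, 0.05, 1e-3)
  amp <- 4 * find_threshold("surrogate")
  rec <- run_tissue("surrogate", geometry = g,
                    stimuli = list(stimulus_region(region_columns(g), 0,
                                                   amplitude = amp)),
                    duration = 600, frame_dt = 0, stop_when_quiescent = TRUE)
  acts <- rec$activations
  node <- with(acts, atriawave:::node_index(ix, iy, g$ny))
  expect_identical(anyDuplicated(node), 0L)  # no re-activation anywhere
  expect_identical(sort(node), seq_len(80L * 10L))  # full capture
})

test_that("CV scales like sqrt(D) and drops when INa is blocked", {
  surrogate_model(140)
  cv1 <- measure_cv("surrogate", D = 1e-3, nx = 120, ny = 9, dx = 0.05,
                    duration = 500)$cv
  cv2 <- measure_cv("surrogate", D = 2e-3, nx = 120, ny = 9, dx = 0.05,
                    duration = 500)$cv
  expect_lt(abs(cv2 / cv1 - sqrt(2)), 0.05 * sqrt(2))
  # Courtemanche at the calibrated D: 25% INa slows conduction
  cal <- crn_cv_calibration()
  cv_ina <- measure_cv("courtemanche", scaling(INa = 0.25), D = cal$D)$cv
  expect_lt(cv_ina, cal$cv)
})

test_that("the CFL bound is enforced at configuration time with a clear message", {
  g <- tissue_geometry(10, 10, 0.02, 2e-3)
  expect_error(run_tissue("surrogate", geometry = g, duration = 10,
                          dt = 0.1, frame_dt = 0),
               "stability bound")
})

test_that("stimulus region helpers address the expected nodes", {
  g <- tissue_geometry(6, 4, 0.05, 1e-3)
  expect_identical(region_columns(g, 1:2), 1:8)
  q <- region_quadrant(g)  # columns 1..3, rows 1..2
  expect_identical(sort(q), sort(as.integer(c(1, 2, 5, 6, 9, 10))))
})

test_that("S1S2 far outside refractoriness propagates and extinguishes without reentry", {
  surrogate_model(140)
  g <- tissue_geometry(40, 40, 0.05, 1e-3)
  rec <- run_s1s2("surrogate", NULL, g, s1s2_interval = 500, duration = 1500,
                  frame_dt = 25)
  out <- classify_outcome(rec, 1500)
  expect_identical(out$class, "NO_REENTRY")
  expect_identical(rec$stopped, "quiescent")
  # deep inside refractoriness: no capture beyond the stimulated quadrant
  rec2 <- run_s1s2("surrogate", NULL, g, s1s2_interval = 120,
                   duration = 1500, frame_dt = 25)
  out2 <- classify_outcome(rec2, 1500)
  expect_identical(out2$class, "NO_CAPTURE")
})
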