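test_that("favourable strains with perfused, bone-adjacent tissue drive ossification", {
  rb <- rule_base()
  out <- evaluate_rules(reg_input(1, 5, perf = 90, nbone = 80, nperf = 50), rb)
  expect_gt(out$d_bone, 0)
  expect_false(out$destroyed)
  # angiogenesis fires in the same window
  expect_gt(out$d_perfusion, 0)
})

test_that("damaging strain states destroy tissue and shut down angiogenesis", {
  rb <- rule_base()
  out <- evaluate_rules(reg_input(5, 35), rb)
  expect_true(out$destroyed)
  expect_lte(out$d_perfusion, 0)
  expect_equal(out$d_bone, 0)
  # compressive states are not destroyed by default (tensile rupture only)
  out_c <- evaluate_rules(reg_input(-5, 35), rb)
  expect_false(out_c$destroyed)
  rb_sym <- rule_base(compressive_destruction = TRUE)
  expect_true(evaluate_rules(reg_input(-5, 35), rb_sym)$destroyed)
})

test_that("destruction needs both invariants by default, either on request", {
  rb <- rule_base()
  expect_false(evaluate_rules(reg_input(5, 5), rb)$destroyed)   # eps only
  expect_false(evaluate_rules(reg_input(1, 35), rb)$destroyed)  # gamma only
  rb_e <- rule_base(destruction = "either")
  expect_true(evaluate_rules(reg_input(5, 5), rb_e)$destroyed)
  expect_true(evaluate_rules(reg_input(1, 35), rb_e)$destroyed)
})

test_that("a fully quiescent avascular state produces no change", {
  out <- evaluate_rules(reg_input(0, 0), rule_base())
  expect_equal(out$d_perfusion, 0)
  expect_equal(out$d_cart, 0)
  expect_equal(out$d_bone, 0)
  expect_false(out$destroyed)
})

test_that("no spontaneous generation without perfusion or neighbours", {
  rb <- rule_base()
  # sweep the favourable window with all vascular/bone context at zero
  grid <- expand.grid(eps = c(0.5, 1, 2, 3), gam = c(0, 5, 10, 17))
  out <- evaluate_rules(reg_input(grid$eps, grid$gam), rb)
  expect_true(all(out$d_bone <= 0))
  expect_true(all(out$d_perfusion <= 0))
})

test_that("bone response is monotone in perfusion within the favourable window", {
  rb <- rule_base()
  perf <- seq(0, 100, by = 10)
  out <- evaluate_rules(reg_input(rep(1, length(perf)), 5, perf = perf,
                                  nperf = 60, nbone = 60), rb)
  expect_true(all(diff(out$d_bone) >= -1e-12))
})

test_that("moderate shear drives chondrogenesis; perfused cartilage calcifies", {
  rb <- rule_base()
  chon <- evaluate_rules(reg_input(1, 17, perf = 10, nperf = 30), rb)
  expect_gt(chon$d_cart, 0)
  calc <- evaluate_rules(reg_input(0.5, 3, perf = 80, cart = 60,
                                   nperf = 60, nbone = 60), rb)
  expect_gt(calc$d_bone, 0)
  expect_lt(calc$d_cart, 0)
})

test_that("regulation bookkeeping conserves concentrations", {
  st <- tissue_state(conn = 50, bone = 50, perfusion = 40)
  out <- data.frame(d_perfusion = 5, d_cart = 0, d_bone = 10,
                    destroyed = FALSE)
  new <- apply_regulation(st, out)
  expect_equal(new$conn, 40)
  expect_equal(new$bone, 60)
  expect_equal(new$perfusion, 45)
  expect_equal(new$conn + new$cart + new$bone + new$cort, 100,
               tolerance = 1e-6)

  # destruction resets to unperfused connective tissue
  gone <- apply_regulation(st, data.frame(d_perfusion = 0, d_cart = 0,
                                          d_bone = 0, destroyed = TRUE))
  expect_equal(gone$conn, 100)
  expect_equal(gone$perfusion, 0)

  # calcification sources bone from cartilage before connective tissue
  st2 <- tissue_state(conn = 20, cart = 60, bone = 20, perfusion = 80)
  out2 <- data.frame(d_perfusion = 0, d_cart = -5, d_bone = 5,
                     destroyed = FALSE)
  new2 <- apply_regulation(st2, out2)
  expect_equal(new2$cart, 55)
  expect_equal(new2$bone, 25)
  expect_equal(new2$conn, 20)
})

test_that("concentration conservation holds across random update sequences", {
  rb <- rule_base()
  set.seed(42)
  st <- data.frame(conn = rep(100, 50), cart = 0, bone = 0, cort = 0,
                   perfusion = 0)
  for (k in 1:30) {
    inp <- reg_input(eps = runif(50, -6, 6), gam = runif(50, 0, 40),
                     perf = st$perfusion, cart = st$cart, bone = st$bone,
                     nperf = runif(50, 0, 100), nbone = runif(50, 0, 100))
    out <- evaluate_rules(inp, rb)
    st <- apply_regulation(st, out)
    expect_true(all(abs(st$conn + st$cart + st$bone + st$cort - 100) < 1e-6))
    expect_true(all(st$perfusion >= 0 & st$perfusion <= 100))
    expect_true(all(st$conn >= -1e-9 & st$cart >= -1e-9 & st$bone >= -1e-9))
  }
})

test_that("neighbourhood aggregation preserves constants and excludes self", {
  m <- build_mesh(do_geometry(current_gap = 3), callus_size = 0.5)
  n <- nrow(m$elem)
  W <- neighborhood_weights(m, sigma = 0.5)
  expect_equal(as.vector(W %*% rep(100, n)), rep(100, n), tolerance = 1e-9)
  expect_true(all(Matrix::diag(W) == 0))
  # an isolated nonzero element does not see itself
  f <- numeric(n); f[5] <- 50
  expect_equal(neighborhood_aggregate(m, f, sigma = 0.5, W = W)[5], 0)
})

test_that("cortical edges seed the neighbourhood fields of adjacent callus", {
  m <- build_mesh(do_geometry(), callus_size = 0.25)
  perf <- ifelse(m$region == "callus", 0, 100)
  agg <- neighborhood_aggregate(m, perf, sigma = 0.25)
  callus <- which(m$region == "callus")
  z <- m$centroids[callus, "z"]
  edge <- callus[z < 0.3 | z > 0.7]
  mid <- callus[z >= 0.3 & z <= 0.7]
  expect_gt(min(agg[edge]), 0)
  expect_gt(mean(agg[edge]), mean(agg[mid]))
})
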