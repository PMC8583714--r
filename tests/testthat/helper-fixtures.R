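# Hand-built single-element mesh (annular ring element away from the axis):
# the smallest structure solve_event() accepts, used for constitutive-level
# oracles.
single_element_mesh <- function(r0 = 6, r1 = 8, z0 = 0, z1 = 1) {
  nodes <- cbind(r = c(r0, r1, r1, r0), z = c(z0, z0, z1, z1))
  structure(list(
    nodes = nodes, elem = matrix(1:4, 1), region = "callus",
    tag = c("bottom_fixed", "bottom_fixed", "top_loaded", "top_loaded"),
    centroids = matrix(c((r0 + r1) / 2, (z0 + z1) / 2), 1, 2,
                       dimnames = list(NULL, c("r", "z"))),
    areas = (r1 - r0) * (z1 - z0),
    geometry = do_geometry(current_gap = z1 - z0),
    callus_size = r1 - r0, bone_size = r1 - r0, external_callus = FALSE,
    gap_face_bottom = 1:2, gap_face_top = 3:4), class = "do_mesh")
}

# Closed-form 1-D Prony relaxation response for a linear strain ramp over
# [0, tr] followed by a hold: normalised stress at time t >= tr.
prony_ramp_hold <- function(t, tr, g, tau) {
  s <- 1 - sum(g)
  for (i in seq_along(g))
    s <- s + g[i] * tau[i] / tr * (exp(-(t - tr) / tau[i]) - exp(-t / tau[i]))
  s
}

# regulation input helper
reg_input <- function(eps, gam, perf = 0, cart = 0, bone = 0,
                      nperf = 0, nbone = 0) {
  data.frame(eps_dil = eps, gamma_dist = gam, perfusion = perf,
             c_cart = cart, c_bone = bone, neighbor_perfusion = nperf,
             neighbor_bone = nbone)
}
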