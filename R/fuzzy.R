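#' Fuzzy mechano-regulation rule base
#'
#' The tissue-differentiation controller is a Mamdani fuzzy system over
#' seven state variables: the dilatational (`eps`, %, magnitude) and
#' distortional (`gamma`, %) strain invariants, local blood perfusion,
#' cartilage and bone concentration, and the Gaussian-neighbourhood
#' perfusion (`n_perf`) and bone (`n_bone`) levels. It outputs daily changes
#' in perfusion, cartilage and bone, plus a tissue-destruction flag.
#'
#' The default rule table encodes the processes of the regeneration model:
#' angiogenesis within the favourable strain window (0.01 < eps < 3.4,
#' gamma < 15, vessels growing only from vascularised neighbours),
#' intramembranous ossification in well-perfused tissue adjacent to bone,
#' chondrogenesis in the moderate-shear band (15 <= gamma < 20),
#' endochondral calcification of perfused cartilage, and tissue destruction
#' when both invariants exceed their damage thresholds (eps > 3.4 together
#' with gamma > 20; gamma > 30 is "very high" and additionally shuts down
#' angiogenesis on its own). Memberships are trapezoids holding full value
#' across each stated window, with 10 % tapers outside it.
#'
#' @param memberships Named list: per variable, a named list of trapezoids
#'   `c(a, b, c, d)` (membership rises a->b, holds b->c, falls c->d).
#' @param rules List of rules; each rule is a list with `when` (named
#'   character vector, variable -> term), and either `then` (named character
#'   vector, output -> class among negative/zero/low/high) or
#'   `destroy = TRUE`.
#' @param rates Named numeric: maximum daily rates (\%/day) for outputs
#'   `perfusion`, `cart`, `bone`.
#' @param destruction `"both"` (default): destruction requires eps and gamma
#'   to exceed their thresholds jointly; `"either"`: each alone suffices.
#' @param damage_heal_rate Clearance rate (fraction/day) of necrotic
#'   tissue. Destruction leaves the element fully necrotic (damage fraction
#'   1); necrosis is resorbed at this rate.
#' @param vascular_heal_gain Acceleration of necrosis clearance by the
#'   vascular supply: the effective clearance rate is
#'   `damage_heal_rate * (1 + vascular_heal_gain * n_perf / 100)`. Debris
#'   adjacent to the perfused cortex is resorbed within days, while
#'   avascular mid-gap scar persists for weeks.
#' @param damage_gate Necrotic fraction above which the element cannot
#'   regenerate at all: debris must be largely cleared before granulation
#'   and differentiation resume. Below the gate, differentiation scales
#'   with the intact fraction. Rupture of a large tissue volume therefore
#'   carries a debt lasting into consolidation -- the cost of aggressive
#'   early distraction.
#' @param compressive_destruction Also destroy tissue when the damaging
#'   strain state is compressive (`eps_dil < 0`). Off by default: the damage
#'   thresholds derive from tensile distraction injury, whereas sustained
#'   cyclic compression of soft interzone tissue drives chondrogenesis (the
#'   endochondral route) rather than rupture; vascular inhibition still
#'   applies under compression.
#' @return An object of class `rule_base`.
#' @export
rule_base <- function(memberships = NULL, rules = NULL,
                      rates = c(perfusion = 3, cart = 3, bone = 3),
                      destruction = c("both", "either"),
                      damage_heal_rate = 0.03, vascular_heal_gain = 4,
                      damage_gate = 0.5,
                      compressive_destruction = FALSE) {
  if (damage_heal_rate < 0 || damage_heal_rate > 1)
    stop("damage_heal_rate must lie in [0, 1]")
  if (damage_gate < 0 || damage_gate > 1)
    stop("damage_gate must lie in [0, 1]")
  if (vascular_heal_gain < 0) stop("vascular_heal_gain must be non-negative")
  destruction <- match.arg(destruction)
  if (is.null(memberships)) memberships <- .default_memberships()
  if (is.null(rules)) rules <- .default_rules(destruction)
  if (any(rates < 0)) stop("maximum daily rates must be non-negative")
  for (v in names(memberships))
    for (trm in names(memberships[[v]])) {
      t4 <- memberships[[v]][[trm]]
      if (length(t4) != 4 || is.unsorted(t4[is.finite(t4)]))
        stop("membership ", v, ":", trm, " is not a valid trapezoid")
    }
  for (rl in rules) {
    for (v in names(rl$when))
      if (is.null(memberships[[v]]) ||
          is.null(memberships[[v]][[rl$when[[v]]]]))
        stop("rule refers to unknown membership ", v, ":", rl$when[[v]])
    if (is.null(rl$then) && !isTRUE(rl$destroy))
      stop("rule without consequent")
  }
  structure(list(memberships = memberships, rules = rules, rates = rates,
                 destruction = destruction,
                 damage_heal_rate = damage_heal_rate,
                 vascular_heal_gain = vascular_heal_gain,
                 damage_gate = damage_gate,
                 compressive_destruction = compressive_destruction),
            class = "rule_base")
}

.default_memberships <- function() {
  list(
    eps = list(quiescent = c(0, 0, 0.009, 0.011),
               favorable = c(0.009, 0.01, 3.4, 3.74),
               high = c(3.4, 3.74, Inf, Inf)),
    gamma = list(low = c(0, 0, 15, 16.5),
                 moderate = c(13.5, 15, 20, 22),
                 high = c(20, 22, Inf, Inf),
                 very_high = c(30, 33, Inf, Inf)),
    perfusion = list(low = c(0, 0, 30, 50),
                     high = c(30, 50, 100, 100)),
    cart = list(low = c(0, 0, 20, 40),
                present = c(0, 10, 100, 100),
                high = c(20, 40, 100, 100)),
    bone = list(low = c(0, 0, 30, 50),
                high = c(30, 50, 100, 100)),
    n_perf = list(present = c(0, 20, 100, 100)),
    n_bone = list(present = c(0, 20, 100, 100))
  )
}

.default_rules <- function(destruction = "both") {
  destroy_rules <- if (destruction == "both") {
    list(list(when = c(eps = "high", gamma = "high"), destroy = TRUE))
  } else {
    list(list(when = c(eps = "high"), destroy = TRUE),
         list(when = c(gamma = "high"), destroy = TRUE))
  }
  c(list(
    # angiogenesis: vessels advance from vascularised tissue under
    # favourable strains, slowly so at rest or under moderate shear
    list(when = c(eps = "favorable", gamma = "low", n_perf = "present"),
         then = c(perfusion = "high")),
    list(when = c(eps = "quiescent", gamma = "low", n_perf = "present"),
         then = c(perfusion = "low")),
    list(when = c(eps = "favorable", gamma = "moderate", n_perf = "present"),
         then = c(perfusion = "low")),
    # vascular damage
    list(when = c(eps = "high", gamma = "high"),
         then = c(perfusion = "negative")),
    list(when = c(gamma = "very_high"),
         then = c(perfusion = "negative")),
    # intramembranous ossification and bone maturation
    list(when = c(eps = "favorable", gamma = "low", perfusion = "high",
                  n_bone = "present"),
         then = c(bone = "high")),
    list(when = c(eps = "quiescent", gamma = "low", perfusion = "high",
                  n_bone = "present"),
         then = c(bone = "low")),
    list(when = c(eps = "favorable", gamma = "low", perfusion = "low",
                  n_perf = "present", n_bone = "present"),
         then = c(bone = "low")),
    # chondrogenesis: moderate shear or excessive volumetric strain turns
    # connective tissue into (avascular) cartilage; the destruction override
    # zeroes it again where both invariants are damaging
    list(when = c(gamma = "moderate"),
         then = c(cart = "high")),
    list(when = c(eps = "high"),
         then = c(cart = "high")),
    # endochondral route: cartilage at the ossification front (bone and
    # vessels in the neighbourhood) calcifies into bone even under strains
    # that block intramembranous formation; perfused cartilage remote from
    # the front calcifies under low shear
    list(when = c(cart = "present", n_perf = "present", n_bone = "present"),
         then = c(bone = "low", cart = "negative")),
    list(when = c(cart = "high", perfusion = "high", gamma = "low"),
         then = c(bone = "low", cart = "negative"))
  ), destroy_rules)
}

# trapezoid membership, vectorised over x
.trapmf <- function(x, t4) {
  a <- t4[1]; b <- t4[2]; cc <- t4[3]; d <- t4[4]
  y <- numeric(length(x))
  y[x >= b & x <= cc] <- 1
  up <- x > a & x < b
  if (b > a) y[up] <- (x[up] - a) / (b - a)
  dn <- x > cc & x < d
  if (d > cc) y[dn] <- (d - x[dn]) / (d - cc)
  if (!is.finite(cc)) y[x >= b] <- 1
  y
}

# output set geometry on the normalised universe [-1, 1]
.OUT_SETS <- list(negative = c(-1.5, -1, -0.5), zero = c(-0.5, 0, 0.5),
                  low = c(0, 0.5, 1), high = c(0.5, 1, 1.5))
.OUT_GRID <- seq(-1, 1, length.out = 201)

#' Evaluate the fuzzy tissue-differentiation rules
#'
#' Mamdani inference: min-conjunction of the antecedent memberships,
#' max-aggregation of clipped output sets, centroid defuzzification. Inputs
#' outside membership coverage are clipped to the nearest covered value.
#' The dilatational strain enters through its magnitude: compressive states
#' (consolidation) are regulated by the same windows as tensile ones.
#'
#' @param inp A data.frame with columns `eps_dil`, `gamma_dist`,
#'   `perfusion`, `c_cart`, `c_bone`, `neighbor_perfusion`, `neighbor_bone`
#'   (one row per element), or a single named list/vector.
#' @param rules A [rule_base()].
#' @param step_days Length of the regulation step in days; daily rates are
#'   scaled by this factor (0.5 during twice-daily distraction).
#' @return A data.frame with `d_perfusion`, `d_cart`, `d_bone` (signed,
#'   \%/step) and logical `destroyed`. Destruction overrides the rate
#'   outputs (they are zeroed, perfusion change clamped to <= 0).
#' @export
evaluate_rules <- function(inp, rules, step_days = 1) {
  stopifnot(inherits(rules, "rule_base"))
  if (!is.data.frame(inp)) inp <- as.data.frame(as.list(inp))
  need <- c("eps_dil", "gamma_dist", "perfusion", "c_cart", "c_bone",
            "neighbor_perfusion", "neighbor_bone")
  miss <- setdiff(need, names(inp))
  if (length(miss)) stop("missing inputs: ", paste(miss, collapse = ", "))
  n <- nrow(inp)
  vals <- list(eps = abs(inp$eps_dil),
               gamma = pmax(inp$gamma_dist, 0),
               perfusion = pmin(pmax(inp$perfusion, 0), 100),
               cart = pmin(pmax(inp$c_cart, 0), 100),
               bone = pmin(pmax(inp$c_bone, 0), 100),
               n_perf = pmin(pmax(inp$neighbor_perfusion, 0), 100),
               n_bone = pmin(pmax(inp$neighbor_bone, 0), 100))

  # memoise membership evaluations
  mu <- list()
  getmu <- function(v, trm) {
    key <- paste(v, trm)
    if (is.null(mu[[key]]))
      mu[[key]] <<- .trapmf(vals[[v]], rules$memberships[[v]][[trm]])
    mu[[key]]
  }

  strength <- list()      # per output class, n-vector of max firing strength
  for (o in c("perfusion", "cart", "bone"))
    strength[[o]] <- list(negative = numeric(n), zero = numeric(n),
                          low = numeric(n), high = numeric(n))
  destroyed_strength <- numeric(n)

  for (rl in rules$rules) {
    s <- rep(1, n)
    for (v in names(rl$when)) s <- pmin(s, getmu(v, rl$when[[v]]))
    if (isTRUE(rl$destroy)) {
      destroyed_strength <- pmax(destroyed_strength, s)
    } else {
      for (o in names(rl$then)) {
        cls <- rl$then[[o]]
        strength[[o]][[cls]] <- pmax(strength[[o]][[cls]], s)
      }
    }
  }

  ng <- length(.OUT_GRID)
  defuzz <- function(str) {
    aggm <- NULL
    for (cls in names(.OUT_SETS)) {
      s <- str[[cls]]
      if (all(s == 0)) next
      tri <- .trapmf(.OUT_GRID, .OUT_SETS[[cls]][c(1, 2, 2, 3)])
      clip <- pmin(matrix(s, n, ng), matrix(tri, n, ng, byrow = TRUE))
      aggm <- if (is.null(aggm)) clip else pmax(aggm, clip)
    }
    if (is.null(aggm)) return(numeric(n))
    num <- as.vector(aggm %*% .OUT_GRID)
    den <- rowSums(aggm)
    ifelse(den > 1e-12, num / den, 0)
  }
  d <- data.frame(
    d_perfusion = defuzz(strength$perfusion) * rules$rates["perfusion"],
    d_cart = defuzz(strength$cart) * rules$rates["cart"],
    d_bone = defuzz(strength$bone) * rules$rates["bone"]
  ) * step_days
  if (!isTRUE(rules$compressive_destruction))
    destroyed_strength[inp$eps_dil < 0] <- 0
  destroyed <- destroyed_strength > 0.5
  d$d_perfusion[destroyed] <- pmin(d$d_perfusion[destroyed], 0)
  d$d_cart[destroyed] <- 0
  d$d_bone[destroyed] <- 0
  d$destroyed <- destroyed
  rownames(d) <- NULL
  d
}

#' Gaussian-kernel neighbourhood aggregation
#'
#' For each element, the Gaussian-distance-weighted mean of a per-element
#' field over all other elements within `3 * sigma` (centroid distances),
#' excluding the element itself. Cortex and marrow elements participate as
#' sources, which is how perfusion and osteogenic signals enter the callus
#' from the fragment edges.
#'
#' @param mesh A `do_mesh`.
#' @param field Numeric vector, one value per element.
#' @param sigma Kernel width in mm.
#' @param W Optional precomputed weight matrix from
#'   [neighborhood_weights()]; pass it when aggregating several fields on
#'   one mesh.
#' @return Numeric vector of aggregated values.
#' @export
neighborhood_aggregate <- function(mesh, field, sigma = mesh$callus_size,
                                   W = NULL) {
  stopifnot(inherits(mesh, "do_mesh"))
  if (length(field) != nrow(mesh$elem))
    stop("field must have one value per element")
  if (is.null(W)) W <- neighborhood_weights(mesh, sigma)
  as.vector(W %*% field)
}

#' @rdname neighborhood_aggregate
#' @export
neighborhood_weights <- function(mesh, sigma = mesh$callus_size) {
  if (sigma <= 0) stop("sigma must be positive")
  ctr <- mesh$centroids
  n <- nrow(ctr)
  d2 <- outer(ctr[, 1], ctr[, 1], "-")^2 + outer(ctr[, 2], ctr[, 2], "-")^2
  w <- exp(-d2 / (2 * sigma^2))
  w[d2 > (3 * sigma)^2] <- 0
  diag(w) <- 0
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  Matrix::Matrix(w / rs, sparse = TRUE)
}

#' Apply a regulation output to a tissue state
#'
#' Bookkeeping of the differentiation step: perfusion changes are clamped to
#' [0, 100]; new cartilage is recruited from connective tissue; new bone is
#' sourced from cartilage first when the calcification consequent fired
#' (negative `d_cart`), then from connective tissue (intramembranous
#' route). Destruction resets the element to unperfused connective tissue.
#' Concentrations are renormalised to sum to 100.
#'
#' @param state A [tissue_state()] or a data.frame with columns
#'   `conn, cart, bone, cort, perfusion`.
#' @param out A single-row result of [evaluate_rules()] (or a data.frame
#'   matching `state` row for row).
#' @return Updated state, same shape as the input.
#' @export
apply_regulation <- function(state, out) {
  single <- inherits(state, "tissue_state")
  st <- if (single)
    data.frame(conn = state$conn, cart = state$cart, bone = state$bone,
               cort = state$cort, perfusion = state$perfusion)
  else as.data.frame(state)
  out <- as.data.frame(out)
  if (nrow(out) != nrow(st)) stop("state and output sizes differ")

  st$perfusion <- pmin(pmax(st$perfusion + out$d_perfusion, 0), 100)

  db <- pmax(out$d_bone, 0)
  from_cart <- pmin(pmax(-out$d_cart, 0), st$cart, db)
  from_conn <- pmin(db - from_cart, st$conn)
  st$cart <- st$cart - from_cart
  st$conn <- st$conn - from_conn
  st$bone <- st$bone + from_cart + from_conn

  dc <- pmin(pmax(out$d_cart, 0), st$conn)
  st$conn <- st$conn - dc
  st$cart <- st$cart + dc

  if (any(out$destroyed)) {
    i <- out$destroyed
    st$conn[i] <- 100; st$cart[i] <- 0; st$bone[i] <- 0; st$cort[i] <- 0
    st$perfusion[i] <- 0
  }
  tot <- st$conn + st$cart + st$bone + st$cort
  for (cmp in c("conn", "cart", "bone", "cort"))
    st[[cmp]] <- st[[cmp]] / tot * 100
  if (single)
    tissue_state(st$conn, st$cart, st$bone, st$cort, st$perfusion)
  else st
}
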