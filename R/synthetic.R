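# Seeded generators for property-style testing: chain/branched heavy-atom
# graphs with SET values near 1 (the range observed for saturated carbons),
# optional single heteroatom with a carbonyl-like polar group, and noisy
# linear descriptor -> log P datasets with known ground truth.

.with_seed <- function(seed, fn) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  fn()
}

#' Specification for a synthetic molecule
#'
#' Captures everything needed to reproduce one synthetic molecule draw:
#' identical specs (including the mandatory seed) give identical output.
#' Defaults emulate the studied compounds: 0.85--1.05 SET values for
#' carbons (spread 0.05 about 0.95), carbonyl-like polar groups
#' (`Q_C` near +0.22 e, `Q_X` near -0.29 e, bond length 1.2--1.45
#' Angstrom) and molecular dipole moments of 1--3 Debye.
#'
#' @param n_atoms number of heavy atoms (>= 1).
#' @param topology `"chain"` or `"branched"` (random tree, max degree 4).
#' @param heteroatom_position optional atom index to replace with oxygen;
#'   `NULL` for a hydrocarbon.
#' @param set_mean,set_spread mean and spread of the per-atom SET draw.
#' @param mu_range range (Debye) from which the molecular dipole moment
#'   is drawn when a heteroatom is present; use `c(0, 0)` for an apolar
#'   electronic state.
#' @param seed integer seed (mandatory).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(n_atoms, topology = c("chain", "branched"),
                       heteroatom_position = NULL, set_mean = 0.95,
                       set_spread = 0.05, mu_range = c(1, 3), seed) {
  topology <- match.arg(topology)
  if (n_atoms < 1L) stop("n_atoms must be >= 1")
  if (!is.null(heteroatom_position)) {
    if (heteroatom_position < 1L || heteroatom_position > n_atoms) {
      stop("heteroatom_position outside 1..n_atoms")
    }
  }
  structure(list(n_atoms = as.integer(n_atoms), topology = topology,
                 heteroatom_position = heteroatom_position,
                 set_mean = set_mean, set_spread = set_spread,
                 mu_range = mu_range, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Draw a synthetic molecule
#'
#' Generates a connected heavy-atom graph (chain or random tree), per-atom
#' SET values, and -- when a heteroatom is present -- net charges for the
#' polar pair and a dipolar context. All draws come from one stream
#' seeded by the spec.
#'
#' @param spec a [synth_spec()].
#' @return list with `graph` (a [mol_graph()]), `states` (data frame of
#'   `index`, `element`, `net_charge_e`, `set_value`) and `ctx` (a
#'   [dipolar_context()], or `NULL` for hydrocarbons or zero dipole).
#' @examples
#' m <- synth_molecule(synth_spec(6, "chain", heteroatom_position = 3, seed = 7))
#' m$graph
#' @export
synth_molecule <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  .with_seed(spec$seed, function() {
    n <- spec$n_atoms
    bonds <- if (n == 1L) matrix(integer(0), ncol = 2) else {
      parents <- integer(n - 1L)
      deg <- integer(n)
      for (i in 2:n) {
        open <- which(deg[seq_len(i - 1L)] < 4L)
        p <- if (spec$topology == "chain") i - 1L
             else open[sample.int(length(open), 1L)]
        parents[i - 1L] <- p
        deg[p] <- deg[p] + 1L; deg[i] <- deg[i] + 1L
      }
      cbind(parents, 2:n)
    }
    elements <- rep("C", n)
    hp <- spec$heteroatom_position
    if (!is.null(hp)) elements[hp] <- "O"
    g <- mol_graph(elements, bonds)
    sets <- pmax(stats::rnorm(n, spec$set_mean, spec$set_spread), 0.05)
    charges <- rep(NA_real_, n)
    ctx <- NULL
    if (!is.null(hp)) {
      nb <- atom_neighbors(g, hp)
      ci <- nb[1]                       # carbon of the polar pair
      charges[ci] <- stats::runif(1, 0.15, 0.30)
      charges[hp] <- stats::runif(1, -0.35, -0.22)
      d <- stats::runif(1, 1.20, 1.45)
      mu <- stats::runif(1, spec$mu_range[1], spec$mu_range[2])
      if (mu > 0) ctx <- dipolar_context(mu, d, charges[ci], charges[hp])
    }
    list(graph = g,
         states = data.frame(index = seq_len(n), element = elements,
                             net_charge_e = charges, set_value = sets,
                             stringsAsFactors = FALSE),
         ctx = ctx)
  })
}

#' Draw a synthetic descriptor -> log P calibration dataset
#'
#' `y = a + b x + eps`, `eps ~ Normal(0, sigma)`, with `x` uniform over
#' `x_range`. Defaults mirror the alcohol-class calibration conditions
#' (intercept -3.25, slope 0.64, residual scale 0.15 log units, n = 60,
#' descriptor values spanning 2--18).
#'
#' @param a intercept.
#' @param b slope.
#' @param sigma noise standard deviation (>= 0), log units.
#' @param n number of points (>= 3).
#' @param seed integer seed (mandatory).
#' @param x_range range of the descriptor draw.
#' @return list with numeric vectors `x` and `y` and the generating
#'   parameters.
#' @export
synth_calibration_dataset <- function(a = -3.25, b = 0.64, sigma = 0.15,
                                      n = 60, seed, x_range = c(2, 18)) {
  if (n < 3L) stop("n must be >= 3")
  if (sigma < 0) stop("sigma must be >= 0")
  .with_seed(seed, function() {
    x <- stats::runif(n, x_range[1], x_range[2])
    y <- a + b * x + stats::rnorm(n, 0, sigma)
    list(x = x, y = y, a = a, b = b, sigma = sigma, n = as.integer(n),
         seed = as.integer(seed))
  })
}
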