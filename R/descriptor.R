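#' Equivalent local dipole moment of a C--heteroatom group
#'
#' \eqn{\mu_F = d\,|Q_C - Q_X|}: the bond length times the absolute
#' difference between the net atomic charges of the group carbon and the
#' heteroatom. This is the characteristic local dipole against which the
#' molecular dipole moment is compared in [dipolar_function()].
#'
#' @param d C--heteroatom bond length in Angstrom (> 0).
#' @param q_c net atomic charge of the group carbon, in e.
#' @param q_x net atomic charge of the heteroatom, in e.
#' @return `mu_f` (>= 0), in Debye-equivalent units.
#' @examples
#' local_dipole(1.2342, 0.224, -0.288) # 0.6319 for a ketone carbonyl
#' @export
local_dipole <- function(d, q_c, q_x) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d <= 0) {
    stop("bond length 'd' must be a positive number (Angstrom)")
  }
  d * abs(q_c - q_x)
}

#' Dipolar correction factor
#'
#' \eqn{A_\mu = 1 + \log_{10}(1 + \mu/\mu_F)}. Equals 1 when the molecular
#' dipole moment is zero and grows logarithmically with \eqn{\mu}; it
#' multiplies the SET values of heteroatoms and of carbons bonded to them.
#'
#' @param mu molecular dipole moment in Debye (>= 0).
#' @param mu_f equivalent local dipole moment from [local_dipole()] (> 0
#'   whenever `mu > 0`).
#' @return `a_mu` (>= 1), dimensionless.
#' @examples
#' dipolar_function(2.6790, 0.63191) # 1.7193
#' @export
dipolar_function <- function(mu, mu_f) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0) {
    stop("dipole moment 'mu' must be a non-negative number (Debye)")
  }
  if (mu == 0) return(1)
  if (!is.numeric(mu_f) || length(mu_f) != 1L || is.na(mu_f) || mu_f <= 0) {
    stop("mu_f is zero (or undefined) while mu > 0: the dipolar factor is ",
         "singular; supply a polar-group definition with distinct charges")
  }
  1 + log10(1 + mu / mu_f)
}

#' Molecule-level dipolar context
#'
#' Bundles the quantities entering the dipolar correction: the molecular
#' dipole moment, the polar-group bond length and net charges, and the
#' derived `mu_f` and `a_mu`.
#'
#' @param mu molecular dipole moment, Debye.
#' @param d C--heteroatom bond length, Angstrom.
#' @param q_c,q_x net charges (e) of the group carbon and heteroatom.
#' @return object of class `dipolar_context` with fields `mu`, `d`, `q_c`,
#'   `q_x`, `mu_f`, `a_mu`.
#' @export
dipolar_context <- function(mu, d, q_c, q_x) {
  mu_f <- local_dipole(d, q_c, q_x)
  structure(list(mu = mu, d = d, q_c = q_c, q_x = q_x, mu_f = mu_f,
                 a_mu = dipolar_function(mu, mu_f)),
            class = "dipolar_context")
}

#' @export
print.dipolar_context <- function(x, ...) {
  cat(sprintf("dipolar context: mu = %.4f D, d = %.4f A, Q_C = %.3f e, Q_X = %.3f e\n",
              x$mu, x$d, x$q_c, x$q_x))
  cat(sprintf("  mu_F = %.4f, A_mu = %.4f\n", x$mu_f, x$a_mu))
  invisible(x)
}

#' Charge-to-SET mapping
#'
#' A `set_map` converts net atomic charges into per-atom SET values. Two
#' modes are supported, separately or combined: per-category linear
#' coefficients (`set = slope * Q + intercept`, one pair per atom category
#' as produced by [classify_atoms()]), and an explicit per-atom override
#' table used when calibrated reference SET values are available. The
#' packaged reference data use overrides, since the per-category linear
#' coefficients belong to the upstream parameterisation of the index and
#' are treated here as configuration.
#'
#' @param coefficients optional data frame with columns `category`,
#'   `slope`, `intercept` and optionally `q_min`, `q_max` giving the charge
#'   domain over which the line is valid.
#' @param overrides optional named numeric vector (names are atom indices
#'   as characters) or numeric vector indexed by atom, of explicit SET
#'   values.
#' @return object of class `set_map`.
#' @export
set_map <- function(coefficients = NULL, overrides = NULL) {
  if (!is.null(coefficients)) {
    coefficients <- as.data.frame(coefficients)
    need <- c("category", "slope", "intercept")
    if (!all(need %in% names(coefficients))) {
      stop("'coefficients' needs columns: ", paste(need, collapse = ", "))
    }
  }
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    if (is.null(names(overrides))) {
      names(overrides) <- as.character(seq_along(overrides))
    }
    if (any(!is.finite(overrides) | overrides <= 0)) {
      stop("override SET values must be strictly positive")
    }
  }
  structure(list(coefficients = coefficients, overrides = overrides),
            class = "set_map")
}

#' SET value from a net atomic charge
#'
#' Evaluates the linear charge-to-SET relationship of a [set_map()] for
#' one atom, or returns the atom's explicit override when one is present
#' (overrides take precedence).
#'
#' @param q net atomic charge in e (may be `NA` when an override exists).
#' @param category atom category label (see [classify_atoms()]).
#' @param map a [set_map()].
#' @param index optional atom index used to look up overrides.
#' @return strictly positive SET value.
#' @export
set_from_charge <- function(q, category, map, index = NULL) {
  stopifnot(inherits(map, "set_map"))
  if (!is.null(index) && !is.null(map$overrides)) {
    ov <- map$overrides[as.character(index)]
    if (!is.na(ov)) return(unname(ov))
  }
  co <- map$coefficients
  if (is.null(co) || !category %in% co$category) {
    stop("set_map has no coefficients (or override) for category '",
         category, "'")
  }
  row <- co[match(category, co$category), ]
  if (is.na(q)) stop("net charge required for category '", category,
                     "' (no override present)")
  if (!is.null(row$q_min) && !is.na(row$q_min) &&
      (q < row$q_min || q > row$q_max)) {
    stop(sprintf("net charge %.4f outside the declared domain [%.4f, %.4f] for '%s'",
                 q, row$q_min, row$q_max, category))
  }
  val <- row$slope * q + row$intercept
  if (!is.finite(val) || val <= 0) {
    stop(sprintf("charge-to-SET mapping produced a non-positive value (%.4f) for category '%s'",
                 val, category))
  }
  val
}

#' Apply the dipolar scaling to per-atom SET values
#'
#' Multiplies the SET values of the atoms in `scaled` (by default the
#' heteroatoms and their attached carbons) by the dipolar factor `a_mu`;
#' all other atoms keep their raw SET value.
#'
#' @param g a [mol_graph()].
#' @param set_values numeric vector of raw SET values, one per atom.
#' @param ctx a [dipolar_context()], or `NULL` for apolar molecules
#'   (`a_mu = 1`).
#' @param scaled integer vector of atom indices to scale; defaults to
#'   [dipole_scaled_atoms()].
#' @return numeric vector of effective SET values, one per atom.
#' @export
effective_sets <- function(g, set_values, ctx = NULL,
                           scaled = dipole_scaled_atoms(g)) {
  stopifnot(inherits(g, "mol_graph"))
  n <- n_atoms(g)
  set_values <- as.numeric(set_values)
  if (length(set_values) != n) {
    stop("need exactly one SET value per atom (", n, ")")
  }
  if (length(scaled) && (any(scaled < 1) || any(scaled > n))) {
    stop("'scaled' contains atom indices outside the graph")
  }
  a_mu <- if (is.null(ctx)) 1 else ctx$a_mu
  if (a_mu < 1) stop("a_mu must be >= 1")
  eff <- set_values
  eff[scaled] <- eff[scaled] * a_mu
  bad <- which(!is.finite(eff) | eff <= 0)
  if (length(bad)) {
    stop("non-positive effective SET value at atom(s) ",
         paste(bad, collapse = ", "), "; the logarithm is undefined")
  }
  eff
}

#' Contribution of one atom to the index
#'
#' The atom's own effective SET plus the base-10 logarithm of each
#' neighbour's effective SET.
#'
#' @param i atom index.
#' @param g a [mol_graph()].
#' @param eff numeric vector of effective SET values (see
#'   [effective_sets()]).
#' @return the atom contribution \eqn{I_{SET,i}}.
#' @export
atom_contribution <- function(i, g, eff) {
  stopifnot(inherits(g, "mol_graph"))
  nb <- atom_neighbors(g, i)
  vals <- eff[c(i, nb)]
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("missing effective SET value for atom ", i, " or a neighbour")
  }
  eff[i] + sum(log10(eff[nb]))
}

#' Total electrotopological index
#'
#' Sums the per-atom contributions ([atom_contribution()]) over all heavy
#' atoms. The result is independent of atom ordering.
#'
#' @param g a [mol_graph()].
#' @param eff numeric vector of effective SET values.
#' @return object of class `iset_breakdown`: list with `per_atom` (named
#'   numeric vector of contributions, full precision) and `total`.
#' @export
total_iset <- function(g, eff) {
  stopifnot(inherits(g, "mol_graph"))
  per_atom <- vapply(seq_len(n_atoms(g)), atom_contribution, numeric(1),
                     g = g, eff = eff)
  names(per_atom) <- paste0(g$atoms$element, g$atoms$index)
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 name = g$name),
            class = "iset_breakdown")
}

#' @export
print.iset_breakdown <- function(x, digits = 4, ...) {
  cat("I_SET breakdown", if (!is.null(x$name)) paste0(" for ", x$name),
      "\n", sep = "")
  if (!is.null(x$a_mu)) {
    cat(sprintf("  mu_F = %.*f   A_mu = %.*f\n",
                digits, x$mu_f, digits, x$a_mu))
  }
  tab <- data.frame(atom = names(x$per_atom),
                    contribution = round(x$per_atom, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("  total I_SET = %.*f  (displayed-contribution sum: %.*f)\n",
              digits, x$total, digits, sum(round(x$per_atom, digits))))
  invisible(x)
}

#' Reporting-precision total of a breakdown
#'
#' Sum of the per-atom contributions rounded to the display precision (4
#' decimals by default). Reference tabulations of the index are built by
#' summing contributions quoted at this precision, so this is the figure
#' to compare against published values; `x$total` carries the
#' full-precision sum.
#'
#' @param x an `iset_breakdown`.
#' @param digits decimal places used for the per-atom contributions.
#' @return numeric scalar.
#' @export
displayed_total <- function(x, digits = 4) {
  stopifnot(inherits(x, "iset_breakdown"))
  sum(round(x$per_atom, digits))
}

#' Read an electronic-state sidecar file
#'
#' The electronic state of a molecule (net atomic charges, molecular
#' dipole moment, polar-group geometry, optional precomputed SET values)
#' comes from an external semi-empirical calculation and is supplied as a
#' keyed YAML/JSON sidecar with fields `dipole_debye`, optional
#' `polar_group` (`carbon`, `heteroatom`, `bond_length_angstrom`) and an
#' `atoms` list of rows `index`, `element`, optional `net_charge_e`,
#' optional `set_value`.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` sidecar file.
#' @return a list with components `name`, `dipole_debye`, `polar_group`
#'   and `atoms` (data frame).
#' @export
read_state <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::fromJSON(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  if (is.null(raw$atoms)) stop("sidecar has no 'atoms' section: ", path)
  atoms <- do.call(rbind, lapply(raw$atoms, function(a) {
    data.frame(index = as.integer(a$index),
               element = as.character(a$element),
               net_charge_e = if (is.null(a$net_charge_e)) NA_real_
                              else as.numeric(a$net_charge_e),
               set_value = if (is.null(a$set_value)) NA_real_
                           else as.numeric(a$set_value),
               stringsAsFactors = FALSE)
  }))
  atoms <- atoms[order(atoms$index), , drop = FALSE]
  if (!identical(atoms$index, seq_len(nrow(atoms)))) {
    stop("sidecar atom indices must be contiguous from 1")
  }
  list(name = raw$name, dipole_debye = as.numeric(raw$dipole_debye),
       polar_group = raw$polar_group, atoms = atoms)
}

.choose_polar_group <- function(groups, g, strategy) {
  if (!is.null(groups$carbon)) groups <- list(groups)   # single group
  if (length(groups) == 1L || strategy == "first") return(groups[[1]])
  if (strategy == "carbonyl") {
    for (grp in groups) {
      ci <- as.integer(grp$carbon); xi <- as.integer(grp$heteroatom)
      k <- which(g$bonds$i == min(ci, xi) & g$bonds$j == max(ci, xi))
      if (length(k) && g$bonds$order[k] == 2 &&
          toupper(g$atoms$element[xi]) == "O") {
        return(grp)
      }
    }
    stop("mu_f_strategy 'carbonyl' found no C=O pair among the polar groups; ",
         "use strategy 'first' or supply a single polar_group")
  }
  stop("unknown mu_f_strategy: ", strategy)
}

#' Compute the electrotopological index for one molecule
#'
#' End-to-end pipeline: parse/accept the structure, attach the electronic
#' state, derive per-atom SET values (explicit `set_value` entries act as
#' overrides; otherwise the [set_map()] is applied to the net charges),
#' evaluate the local dipole moment and the dipolar factor from the polar
#' group, scale the SET values of the heteroatoms and their attached
#' carbons, and aggregate. Molecules without heteroatoms, or with a zero
#' dipole moment, bypass the dipolar correction (`a_mu = 1`).
#'
#' @param structure a [mol_graph()], a SMILES string, or a path to a
#'   `.smi`/`.sdf`/`.mol` file containing a single record.
#' @param state a sidecar list from [read_state()], or a path to one.
#' @param map optional [set_map()] supplying charge-to-SET coefficients
#'   for atoms without explicit `set_value` entries.
#' @param mu_f_strategy how to pick the polar group when the sidecar lists
#'   several: `"carbonyl"` (default; the C=O pair) or `"first"`.
#' @return an `iset_breakdown` with additional fields `mu_f`, `a_mu`,
#'   `effective_set` and `scaled_atoms`.
#' @examples
#' smi <- system.file("extdata", "hexan3one.smi", package = "isetlogp")
#' st  <- system.file("extdata", "hexan3one_state.yaml", package = "isetlogp")
#' compute_descriptor(smi, st)
#' @export
compute_descriptor <- function(structure, state, map = NULL,
                               mu_f_strategy = c("carbonyl", "first")) {
  mu_f_strategy <- match.arg(mu_f_strategy)
  g <- if (inherits(structure, "mol_graph")) structure
       else if (file.exists(structure)) {
         gs <- read_structures(structure)
         if (length(gs) != 1L) stop("expected a single structure record in ",
                                    structure)
         gs[[1]]
       } else parse_structure(structure, format = "smiles")
  st <- if (is.character(state)) read_state(state) else state
  if (nrow(st$atoms) != n_atoms(g)) {
    stop("structure/state mismatch: graph has ", n_atoms(g),
         " heavy atoms but the sidecar lists ", nrow(st$atoms))
  }
  if (!identical(toupper(st$atoms$element), toupper(g$atoms$element))) {
    stop("structure/state mismatch: element symbols disagree at atom(s) ",
         paste(which(toupper(st$atoms$element) != toupper(g$atoms$element)),
               collapse = ", "))
  }
  cls <- classify_atoms(g)
  raw <- st$atoms$set_value
  missing_set <- which(is.na(raw))
  for (i in missing_set) {
    if (is.null(map)) {
      stop("atom ", i, " has no set_value and no set_map was supplied")
    }
    raw[i] <- set_from_charge(st$atoms$net_charge_e[i], cls$category[i], map,
                              index = i)
  }
  scaled <- dipole_scaled_atoms(g)
  mu <- st$dipole_debye
  ctx <- NULL
  if (length(scaled) && !is.null(mu) && !is.na(mu) && mu > 0) {
    if (is.null(st$polar_group)) {
      stop("polar molecule with mu > 0 but the sidecar defines no polar_group")
    }
    grp <- .choose_polar_group(st$polar_group, g, mu_f_strategy)
    ci <- as.integer(grp$carbon); xi <- as.integer(grp$heteroatom)
    q_c <- st$atoms$net_charge_e[ci]; q_x <- st$atoms$net_charge_e[xi]
    if (is.na(q_c) || is.na(q_x)) {
      stop("polar_group atoms must carry net_charge_e values")
    }
    ctx <- dipolar_context(mu, as.numeric(grp$bond_length_angstrom), q_c, q_x)
  }
  eff <- effective_sets(g, raw, ctx, scaled = scaled)
  out <- total_iset(g, eff)
  out$name <- if (!is.null(st$name)) st$name else g$name
  out$mu_f <- if (is.null(ctx)) NA_real_ else ctx$mu_f
  out$a_mu <- if (is.null(ctx)) 1 else ctx$a_mu
  out$effective_set <- eff
  out$scaled_atoms <- if (is.null(ctx)) integer(0) else scaled
  out
}
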