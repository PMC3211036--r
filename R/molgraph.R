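#' Hydrogen-suppressed molecular graph
#'
#' Constructs a `mol_graph`, the labelled heavy-atom graph on which the
#' electrotopological index is evaluated. Atoms are indexed contiguously
#' from 1; hydrogens are never part of the graph. Bond order is retained as
#' an annotation only (a C=O is a single adjacency in the index
#' aggregation) and optional bond lengths (in Angstrom) may be attached to
#' individual bonds.
#'
#' @param elements character vector of element symbols, one per heavy atom.
#' @param bonds two-column integer matrix (or data.frame) of bonded atom
#'   index pairs.
#' @param orders optional numeric vector of bond orders, recycled to the
#'   number of bonds; defaults to 1.
#' @param bond_lengths optional numeric vector of bond lengths in Angstrom,
#'   parallel to the rows of `bonds` (`NA` allowed).
#' @param name optional molecule name.
#' @return an object of class `mol_graph` with components `atoms` (data
#'   frame of `index`, `element`), `bonds` (data frame of `i`, `j`,
#'   `order`, `length`) and `name`.
#' @examples
#' g <- mol_graph(c("C", "C", "O"), rbind(c(1, 2), c(2, 3)))
#' atom_neighbors(g, 2)
#' @export
mol_graph <- function(elements, bonds, orders = 1, bond_lengths = NULL,
                      name = NULL) {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("a molecule must contain at least one heavy atom")
  if (any(toupper(elements) == "H")) {
    stop("hydrogens are not allowed in a hydrogen-suppressed graph")
  }
  bonds <- if (is.null(bonds) || NROW(bonds) == 0L) {
    matrix(integer(0), ncol = 2L)
  } else {
    as.matrix(bonds)[, 1:2, drop = FALSE]
  }
  storage.mode(bonds) <- "integer"
  nb <- nrow(bonds)
  if (nb > 0L) {
    if (any(is.na(bonds)) || any(bonds < 1L) || any(bonds > n)) {
      stop("bond indices must reference existing atoms (1..", n, ")")
    }
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) stop("duplicate bonds are not allowed")
  }
  orders <- rep_len(as.numeric(orders), max(nb, 1L))[seq_len(nb)]
  lengths <- if (is.null(bond_lengths)) rep(NA_real_, nb) else {
    rep_len(as.numeric(bond_lengths), nb)
  }
  g <- structure(
    list(
      atoms = data.frame(index = seq_len(n), element = elements,
                         stringsAsFactors = FALSE),
      bonds = data.frame(i = pmin(bonds[, 1], bonds[, 2]),
                         j = pmax(bonds[, 1], bonds[, 2]),
                         order = orders, length = lengths),
      name = name
    ),
    class = "mol_graph"
  )
  if (!.is_connected(g)) {
    stop("disconnected structure: mixtures/multi-fragment records are not supported")
  }
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("mol_graph", if (!is.null(x$name)) paste0("'", x$name, "'") else "",
      ": ", n_atoms(x), " heavy atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  cat("  formula (heavy atoms): ",
      paste(names(table(x$atoms$element)), table(x$atoms$element),
            sep = "", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param g a [mol_graph()].
#' @return integer atom count.
#' @export
n_atoms <- function(g) nrow(g$atoms)

.is_connected <- function(g) {
  n <- n_atoms(g)
  if (n == 1L) return(TRUE)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nxt <- adj[[v]][!seen[adj[[v]]]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  all(seen)
}

#' Parse a structure record into a molecular graph
#'
#' Reads a single SMILES string or an MDL MOL/SDF (V2000) record and
#' returns the hydrogen-suppressed heavy-atom graph. Parsing is delegated
#' to ChemmineR (SMILES conversion through Open Babel); explicit hydrogens
#' in SDF input are collapsed before graph construction. Multi-record SDF
#' input is handled by [read_structures()].
#'
#' @param record character scalar: a SMILES string (optionally followed by
#'   whitespace and a name), or the full text of one MOL/SDF record.
#' @param format `"smiles"` or `"sdf"`.
#' @param name optional molecule name (overrides any name in the record).
#' @return a [mol_graph()].
#' @examples
#' g <- parse_structure("CCC(=O)CCC 3-hexanone")
#' n_atoms(g) # 7 heavy atoms
#' @export
parse_structure <- function(record, format = c("smiles", "sdf"), name = NULL) {
  format <- match.arg(format)
  if (!is.character(record) || length(record) != 1L) {
    stop("'record' must be a single character string")
  }
  if (format == "smiles") {
    parts <- strsplit(trimws(record), "[[:space:]]+")[[1]]
    smi <- parts[1]
    if (is.null(name) && length(parts) > 1L) {
      name <- paste(parts[-1], collapse = " ")
    }
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smi)),
      error = function(e) stop("unparseable SMILES record: '", smi, "' (",
                               conditionMessage(e), ")", call. = FALSE)
    )
    if (length(sdf) == 0L) stop("unparseable SMILES record: '", smi, "'")
    mol <- sdf[[1]]
  } else {
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf), add = TRUE)
    txt <- record
    if (!grepl("\\$\\$\\$\\$", txt)) txt <- paste0(txt, "\n$$$$\n")
    writeLines(txt, tf)
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(tf)),
      error = function(e) stop("unparseable SDF record (",
                               conditionMessage(e), ")", call. = FALSE)
    )
    if (length(sdf) == 0L) stop("unparseable SDF record")
    if (!ChemmineR::validSDF(sdf)[1]) stop("unparseable SDF record")
    mol <- sdf[[1]]
    if (is.null(name)) {
      hdr <- ChemmineR::header(mol)[1]
      if (nzchar(trimws(hdr))) name <- trimws(hdr)
    }
  }
  .sdf_to_graph(mol, name = name)
}

.sdf_to_graph <- function(mol, name = NULL) {
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  nb <- if (is.null(dim(bb))) 0L else nrow(bb)
  bonds <- if (nb > 0L) {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  } else {
    matrix(integer(0), ncol = 2L)
  }
  orders <- if (nb > 0L) as.numeric(bb[, 3]) else numeric(0)
  heavy <- which(toupper(elements) != "H")
  if (length(heavy) < length(elements)) {       # collapse explicit hydrogens
    remap <- match(seq_along(elements), heavy)
    keep <- bonds[, 1] %in% heavy & bonds[, 2] %in% heavy
    bonds <- cbind(remap[bonds[keep, 1]], remap[bonds[keep, 2]])
    orders <- orders[keep]
    elements <- elements[heavy]
  }
  mol_graph(elements, bonds, orders = orders, name = name)
}

#' Read structures from a file
#'
#' Reads a SMILES file (one record per line, optional name after
#' whitespace) or a multi-record MDL SDF file, returning one graph per
#' record.
#'
#' @param path file path; format is inferred from the extension
#'   (`.smi`/`.smiles` versus `.sdf`/`.mol`) unless given explicitly.
#' @param format `"smiles"`, `"sdf"`, or `NULL` to infer from `path`.
#' @return a list of [mol_graph()] objects (named where names are present).
#' @export
read_structures <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      smi = , smiles = "smiles",
      sdf = , mol = "sdf",
      stop("cannot infer structure format from extension '.", ext, "'")
    )
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    out <- lapply(lines, parse_structure, format = "smiles")
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    recs <- strsplit(txt, "\\$\\$\\$\\$[^\n]*\n?")[[1]]
    recs <- recs[nzchar(trimws(recs))]
    out <- lapply(recs, parse_structure, format = "sdf")
  }
  nms <- vapply(out, function(g) if (is.null(g$name)) "" else g$name, "")
  if (any(nzchar(nms))) names(out) <- nms
  out
}

#' Serialize a molecular graph to an MDL MOL (V2000) block
#'
#' Writes the heavy-atom graph as a minimal V2000 connection table with
#' zeroed coordinates, sufficient to round-trip atom elements and the bond
#' set through [parse_structure()].
#'
#' @param g a [mol_graph()].
#' @return character scalar containing the MOL block.
#' @export
mol_to_sdf <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  n <- n_atoms(g); nb <- nrow(g$bonds)
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        0, 0, 0, g$atoms$element)
  bond_lines <- if (nb > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", g$bonds$i, g$bonds$j,
            as.integer(g$bonds$order))
  } else character(0)
  paste(c(
    if (is.null(g$name)) "" else g$name,
    "  isetlogp", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    atom_lines, bond_lines,
    "M  END"
  ), collapse = "\n")
}

#' Sorted heavy-atom neighbours of an atom
#'
#' @param g a [mol_graph()].
#' @param i atom index (1-based).
#' @return sorted integer vector of neighbouring atom indices.
#' @examples
#' g <- parse_structure("CCC(=O)CCC")
#' atom_neighbors(g, 3) # carbonyl carbon: 2, 4 (O), 5
#' @export
atom_neighbors <- function(g, i) {
  stopifnot(inherits(g, "mol_graph"))
  if (!is.numeric(i) || length(i) != 1L || is.na(i) ||
      i < 1L || i > n_atoms(g) || i != as.integer(i)) {
    stop("unknown atom index: ", i)
  }
  sort(c(g$bonds$j[g$bonds$i == i], g$bonds$i[g$bonds$j == i]))
}

#' Classify atoms of a molecular graph
#'
#' Assigns each atom one category: saturated carbons by heavy-neighbour
#' count (1 -> `CH3`, 2 -> `CH2`, 3 -> `CH`, 4 -> `C_quaternary`; an
#' isolated carbon is treated as `CH3`), and every non-carbon heavy atom is
#' `heteroatom`. Carbons bonded to at least one heteroatom additionally
#' carry the `hetero_adjacent` flag; these are the atoms whose SET values
#' are scaled by the dipolar factor.
#'
#' @param g a [mol_graph()].
#' @return data frame with columns `index`, `element`, `category`,
#'   `hetero_adjacent` (logical), in atom-index order.
#' @examples
#' classify_atoms(parse_structure("CCO")) # ethanol
#' @export
classify_atoms <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  n <- n_atoms(g)
  el <- g$atoms$element
  nbrs <- lapply(seq_len(n), function(i) atom_neighbors(g, i))
  category <- character(n)
  hetero_adjacent <- logical(n)
  for (i in seq_len(n)) {
    if (toupper(el[i]) != "C") {
      category[i] <- "heteroatom"
    } else {
      deg <- length(nbrs[[i]])
      category[i] <- switch(min(deg, 4L) + 1L,
                            "CH3", "CH3", "CH2", "CH", "C_quaternary")
      hetero_adjacent[i] <- any(toupper(el[nbrs[[i]]]) != "C")
    }
  }
  data.frame(index = seq_len(n), element = el, category = category,
             hetero_adjacent = hetero_adjacent, stringsAsFactors = FALSE)
}

#' Atoms subject to the dipolar scaling
#'
#' The default dipole-scaled set: all heteroatoms plus all carbons bonded
#' to a heteroatom.
#'
#' @param g a [mol_graph()].
#' @return sorted integer vector of atom indices (empty for hydrocarbons).
#' @export
dipole_scaled_atoms <- function(g) {
  cls <- classify_atoms(g)
  sort(cls$index[cls$category == "heteroatom" | cls$hetero_adjacent])
}
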