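# Space-group operator handling and fractional/Cartesian conversion.
#
# Macromolecular crystals occupy only the 65 Sohncke space groups (chiral
# molecules admit no mirrors or inversions), so the bundled operator table
# covers exactly those, in their standard and common alternative settings,
# as symbolic x,y,z triplets.

.sg_env <- new.env(parent = emptyenv())

sg_table <- function() {
  if (is.null(.sg_env$table)) {
    path <- system.file("extdata", "spacegroups_sohncke.tsv",
                        package = "tcrlattice", mustWork = TRUE)
    # quote = "": Hall symbols contain double-quote characters
    .sg_env$table <- utils::read.delim(path, stringsAsFactors = FALSE,
                                       quote = "")
  }
  .sg_env$table
}

normalize_sg_symbol <- function(symbol) {
  s <- toupper(trimws(symbol))
  gsub("\\s+", " ", s)
}

#' Parse one symmetry operator triplet
#'
#' Converts a symbolic operator such as `"-x+1/2,-y,z+1/2"` into its rotation
#' matrix and translation vector in fractional coordinates.
#'
#' @param triplet character scalar, comma-separated x,y,z expression.
#' @return list with `R` (3x3 integer-valued matrix) and `t` (length-3
#'   fractional translation).
#' @keywords internal
parse_symop <- function(triplet) {
  parts <- strsplit(gsub("\\s", "", triplet), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    stop("malformed symmetry operator: ", triplet)
  }
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    expr <- tolower(parts[i])
    # split into signed terms: tokens like -x, +y, z, 1/2, -3/4, 0.5
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (term in terms) {
      sign <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (body %in% c("x", "y", "z")) {
        R[i, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        num <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        t[i] <- t[i] + sign * num[1] / num[2]
      } else if (grepl("^[0-9.]+$", body)) {
        t[i] <- t[i] + sign * as.numeric(body)
      } else {
        stop("cannot parse symmetry operator term '", term, "' in ", triplet)
      }
    }
  }
  list(R = R, t = t)
}

#' Look up space-group operators by Hermann-Mauguin symbol
#'
#' @param symbol Hermann-Mauguin symbol as found on a PDB CRYST1 record
#'   (e.g. `"P 21 21 21"`). Case and internal whitespace are tolerated.
#' @return list of operators, each a list with fractional rotation `R` and
#'   translation `t`. The identity is always first.
#' @export
spacegroup_ops <- function(symbol) {
  tab <- sg_table()
  key <- normalize_sg_symbol(symbol)
  hit <- which(toupper(tab$symbol) == key)
  if (length(hit) == 0L) {
    # retry ignoring all whitespace
    hit <- which(gsub(" ", "", toupper(tab$symbol)) == gsub(" ", "", key))
  }
  if (length(hit) == 0L) {
    stop("unknown space-group symbol: '", symbol, "'")
  }
  triplets <- strsplit(tab$operators[hit[1]], ";", fixed = TRUE)[[1]]
  ops <- lapply(triplets, parse_symop)
  # identity first, stable order otherwise
  is_id <- vapply(ops, function(op) {
    all(op$R == diag(3)) && all(abs(op$t) < 1e-9)
  }, logical(1))
  c(ops[is_id], ops[!is_id])
}

#' Orthogonalization matrix of a unit cell
#'
#' Returns the matrix M such that `cartesian = M %*% fractional`, using the
#' standard PDB convention (a along x, b in the xy plane).
#'
#' @param cell numeric length-6: a, b, c in Angstrom; alpha, beta, gamma in
#'   degrees.
#' @return 3x3 matrix.
#' @export
cell_orth_matrix <- function(cell) {
  stopifnot(length(cell) == 6L)
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  if (any(c(a, b, c) <= 0)) stop("unit-cell lengths must be positive")
  ang <- cell[4:6] * pi / 180
  if (any(cell[4:6] <= 0) || any(cell[4:6] >= 180)) {
    stop("unit-cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3]); sg <- sin(ang[3])
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(a, b * cg, c * cb,
           0, b * sg, c * (ca - cb * cg) / sg,
           0, 0,      c * v / sg),
         nrow = 3, byrow = TRUE)
}

#' Convert Cartesian coordinates to fractional
#' @param xyz n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param cell unit-cell parameters, see [cell_orth_matrix()].
#' @return n x 3 matrix of fractional coordinates.
#' @export
cart2frac <- function(xyz, cell) {
  M <- cell_orth_matrix(cell)
  t(solve(M, t(as.matrix(xyz))))
}

#' Convert fractional coordinates to Cartesian
#' @inheritParams cart2frac
#' @param frac n x 3 matrix of fractional coordinates.
#' @return n x 3 matrix of Cartesian coordinates (Angstrom).
#' @export
frac2cart <- function(frac, cell) {
  M <- cell_orth_matrix(cell)
  t(M %*% t(as.matrix(frac)))
}

# apply op (+ lattice shift) to fractional coordinates
apply_symop <- function(frac, op, shift = c(0, 0, 0)) {
  sweep(as.matrix(frac) %*% t(op$R), 2, op$t + shift, `+`)
}

is_identity_op <- function(op) {
  all(op$R == diag(3)) && all(abs(op$t) < 1e-9)
}
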