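PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb",
  "Te", "I", "Xe", "Cs", "Ba", "D")

normalize_element <- function(x) {
  x <- sub("[0-9'].*$", "", trimws(x))
  paste0(toupper(substring(x, 1L, 1L)), tolower(substring(x, 2L)))
}

#' Hydration-cluster model
#'
#' Atom records of an optimized hydration cluster: element symbols with
#' Cartesian coordinates (Angstrom), plus the indices of the central
#' (solute) molecule's atoms. Water oxygens are all oxygens outside the
#' solute selection.
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`.
#' @param solute_selection Integer indices of the solute atoms.
#' @param label Free-text label.
#' @return An object of class `shell_model`.
#' @export
shell_model <- function(atoms, solute_selection = integer(), label = "") {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates", call. = FALSE)
  atoms$element <- normalize_element(atoms$element)
  bad <- setdiff(unique(atoms$element), PERIODIC_SYMBOLS)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  solute_selection <- as.integer(solute_selection)
  if (length(solute_selection) &&
      (min(solute_selection) < 1L || max(solute_selection) > nrow(atoms)))
    stop("solute_selection indices out of range", call. = FALSE)
  structure(list(atoms = atoms, solute_selection = solute_selection,
                 label = label),
            class = "shell_model")
}

#' @export
print.shell_model <- function(x, ...) {
  n_o <- sum(x$atoms$element == "O")
  cat("<shell_model> ", nrow(x$atoms), " atoms (", n_o, " O), ",
      length(x$solute_selection), " solute atoms",
      if (nzchar(x$label)) paste0(" - ", x$label), "\n", sep = "")
  invisible(x)
}

#' Read a hydration-cluster structure
#'
#' XYZ (count line, comment line, then `element x y z` records) or PDB
#' (ATOM/HETATM records, parsed with bio3d). Element symbols are normalized;
#' unknown elements and malformed records raise an error naming the line.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"xyz"`, or `"pdb"`.
#' @param solute_selection Optional solute atom indices; can be set later.
#' @param label Optional label; defaults to the file name.
#' @return A [shell_model()].
#' @export
read_structure <- function(path, format = c("auto", "xyz", "pdb"),
                           solute_selection = integer(), label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("structure file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (is.null(label)) label <- basename(path)
  atoms <- if (format == "xyz") read_xyz_atoms(path) else read_pdb_atoms(path)
  if (!nrow(atoms)) stop("no atoms in ", path, call. = FALSE)
  shell_model(atoms, solute_selection = solute_selection, label = label)
}

read_xyz_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) <= 2L]
  if (length(lines) < 3L)
    stop("malformed XYZ file (fewer than 3 lines): ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("XYZ line 1 is not an atom count in ", path,
                     call. = FALSE)
  rec <- lines[3:(2L + n)]
  if (length(rec) < n || anyNA(rec))
    stop("XYZ file truncated: expected ", n, " atom records in ", path,
         call. = FALSE)
  el <- character(n); xyz <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(rec[i]), "\\s+")[[1L]]
    co <- suppressWarnings(as.numeric(parts[2:4]))
    if (length(parts) < 4L || anyNA(co))
      stop("malformed XYZ record at line ", i + 2L, " of ", path, ": '",
           rec[i], "'", call. = FALSE)
    el[i] <- parts[1L]; xyz[i, ] <- co
  }
  data.frame(element = el, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
}

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e)
                    stop("cannot parse PDB file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  el <- a$elesy
  el[is.na(el) | !nzchar(trimws(el))] <-
    substring(trimws(a$elety[is.na(el) | !nzchar(trimws(el))]), 1L, 1L)
  data.frame(element = el, x = a$x, y = a$y, z = a$z)
}

#' Water oxygens within the first hydration layer
#'
#' Indices of oxygens outside the solute selection whose minimum distance to
#' any solute atom is at most `cutoff`; 3.5 Angstrom is the average
#' thickness of the first hydration layer. Returns an empty set (not an
#' error) when nothing qualifies or the solute selection is empty.
#'
#' @param model A [shell_model()] with a non-empty solute selection.
#' @param cutoff Layer thickness, Angstrom (> 0).
#' @param include_solute_oxygens Count oxygens belonging to the solute
#'   (e.g. a sulfinyl or carboxylate oxygen) as shell members? Default FALSE.
#' @return Integer atom indices.
#' @export
first_shell_oxygens <- function(model, cutoff = 3.5,
                                include_solute_oxygens = FALSE) {
  stopifnot(inherits(model, "shell_model"))
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  sel <- model$solute_selection
  if (!length(sel)) return(integer())
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  ox <- which(model$atoms$element == "O")
  if (!include_solute_oxygens) ox <- setdiff(ox, sel)
  if (!length(ox)) return(integer())
  keep <- vapply(ox, function(i) {
    d2 <- colSums((t(xyz[sel, , drop = FALSE]) - xyz[i, ])^2)
    sqrt(min(d2)) <= cutoff
  }, logical(1L))
  ox[keep]
}

#' Pairwise O...O distances within a hydration layer
#'
#' All pairwise (i < j) Euclidean distances among the selected oxygens,
#' restricted to the hydrogen-bond range (default 2.55-3.00 Angstrom,
#' strong to weak hydrogen bonds). Fewer than two oxygens give an empty
#' list, not an error.
#'
#' @param model A [shell_model()].
#' @param oxygens Integer atom indices (e.g. from [first_shell_oxygens()]).
#' @param r_range Distance range kept, Angstrom.
#' @return Sorted numeric vector of distances.
#' @export
oo_distances <- function(model, oxygens, r_range = c(2.55, 3.00)) {
  stopifnot(inherits(model, "shell_model"))
  oxygens <- as.integer(oxygens)
  if (length(oxygens) < 2L) return(numeric())
  xyz <- as.matrix(model$atoms[oxygens, c("x", "y", "z")])
  d <- as.numeric(stats::dist(xyz))
  sort(d[d >= r_range[1L] & d <= r_range[2L]])
}

#' Normalized interaction-number curve
#'
#' Sorts O...O distances ascending and assigns each the rank divided by the
#' total count, so curves from shells with different numbers of interactions
#' are comparable on [0, 1]. The local slope encodes the spread of distances;
#' an inflection (maximum of the second difference) marks two hydrogen-bond
#' sub-populations.
#'
#' @param distances Non-empty numeric vector of distances, Angstrom.
#' @return Object of class `interaction_curve`: `sorted_distances`,
#'   `normalized_index`, `count`.
#' @export
normalized_interaction_curve <- function(distances) {
  if (!length(distances))
    stop("empty distance list", call. = FALSE)
  d <- sort(as.numeric(distances))
  structure(list(sorted_distances = d,
                 normalized_index = seq_along(d) / length(d),
                 count = length(d)),
            class = "interaction_curve")
}

#' @export
print.interaction_curve <- function(x, ...) {
  cat("<interaction_curve> ", x$count, " interactions, ",
      format(min(x$sorted_distances), digits = 4), "-",
      format(max(x$sorted_distances), digits = 4), " Angstrom\n", sep = "")
  invisible(x)
}

#' @export
plot.interaction_curve <- function(x, ...,
                                   xlab = expression(R[OO] ~ (ring(A))),
                                   ylab = "normalized interaction number") {
  graphics::plot(x$sorted_distances, x$normalized_index, type = "b",
                 pch = 20, xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}
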