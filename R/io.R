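#' Write lambda-dynamics titration records to the tab-separated dialect
#'
#' One file per pH. The file starts with a `# pH<TAB><value>` header line
#' followed by a tab-separated table with columns `frame`, `residue_id`,
#' `lambda`, `chi` (`NA` for single-site residues). Engines differ in their
#' native lambda-trajectory formats; this dialect is the package's
#' engine-agnostic interchange, trivially writable by converters.
#'
#' @param records data frame with columns `frame`, `residue_id`, `lambda`
#'   and optionally `chi`.
#' @param path output file path.
#' @param ph the pH at which the records were sampled, recorded in the
#'   header.
#' @return `path`, invisibly.
#' @export
write_titration_records <- function(records, path, ph) {
  records <- validate_titration_records(records)
  stopifnot(is.numeric(ph), length(ph) == 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pH\t%s", format(ph, digits = 12)), con)
  writeLines("frame\tresidue_id\tlambda\tchi", con)
  lines <- sprintf("%d\t%s\t%s\t%s",
                   as.integer(records$frame), records$residue_id,
                   format(records$lambda, digits = 10, trim = TRUE,
                          scientific = FALSE),
                   ifelse(is.na(records$chi), "NA",
                          format(records$chi, digits = 10, trim = TRUE,
                                 scientific = FALSE)))
  writeLines(lines, con)
  invisible(path)
}

#' Read lambda-dynamics titration records
#'
#' Reads the tab-separated dialect written by [write_titration_records()].
#' Malformed files (missing pH header, missing columns, out-of-range
#' coordinates, non-monotone frame indices) are rejected with context rather
#' than silently coerced.
#'
#' @param path input file path.
#' @return data frame of records with attribute `ph`.
#' @export
read_titration_records <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# pH\t"))
    stop("not a titration record file (expected '# pH\\t<value>' header): ", path)
  ph <- suppressWarnings(as.numeric(sub("^# pH\t", "", header)))
  if (!is.finite(ph)) stop("unparseable pH in header of ", path)
  rec <- utils::read.table(path, skip = 1L, header = TRUE, sep = "\t",
                           colClasses = c("integer", "character",
                                          "numeric", "numeric"),
                           na.strings = "NA")
  rec <- validate_titration_records(rec)
  if (any(!is.na(rec$lambda) & (rec$lambda < 0 | rec$lambda > 1)))
    stop("lambda outside [0,1] in ", path)
  attr(rec, "ph") <- ph
  rec
}

#' Read a (possibly multi-model) PDB file into a list of structure models
#'
#' Each `MODEL ... ENDMDL` block becomes one model; a file without MODEL
#' records yields a single model. Alternate locations are resolved to the
#' highest-occupancy conformer. Parsing is delegated to
#' [bio3d::read.pdb()].
#'
#' @param path PDB file path.
#' @return list of `structure_model` objects, each a list with
#'   `model_index`, `atoms` (data frame with `serial`, `name`, `resname`,
#'   `resno`, `chain`, `x`, `y`, `z`) and `source`.
#' @export
read_pdb_models <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("failed to parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  at <- pdb$atom
  keep <- resolve_altloc(at)
  at <- at[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  idx <- rep(keep, each = 3L) * 3L + rep(c(-2L, -1L, 0L), times = length(keep))
  lapply(seq_len(n_models), function(m) {
    co <- matrix(xyz[m, idx], ncol = 3L, byrow = TRUE)
    if (any(!is.finite(co)))
      stop("non-finite coordinates in model ", m, " of ", path)
    atoms <- data.frame(serial = at$eleno, name = at$elety,
                        resname = at$resid, resno = at$resno,
                        chain = ifelse(is.na(at$chain), "A", at$chain),
                        x = co[, 1L], y = co[, 2L], z = co[, 3L],
                        stringsAsFactors = FALSE)
    structure(list(model_index = m, atoms = atoms, source = path),
              class = "structure_model")
  })
}

# indices of atoms to keep after alternate-location resolution:
# for each (chain, resno, name) keep the conformer with highest occupancy
resolve_altloc <- function(at) {
  alt <- at$alt
  if (is.null(alt)) return(seq_len(nrow(at)))
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- at$o
  occ[is.na(occ)] <- 1
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[alt != ""])) {
    i <- which(key == k)
    if (length(i) > 1L) {
      best <- i[which.max(occ[i])]
      keep[setdiff(i, best)] <- FALSE
    }
  }
  which(keep)
}

#' Write a conformer ensemble as a multi-model PDB file
#'
#' Emits standard fixed-width ATOM records wrapped in MODEL/ENDMDL blocks
#' (coordinates at the format's 3-decimal precision), so the output is
#' readable by any PDB-aware tool and by [read_pdb_models()].
#'
#' @param ensemble a `conformer_ensemble` (see [build_toy_ensemble()]) or a
#'   list of `structure_model` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_models <- function(ensemble, path) {
  models <- as_structure_models(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in models) {
    a <- m$atoms
    writeLines(sprintf("MODEL     %4d", m$model_index), con)
    # PDB v3 alignment: atom names of <4 chars start in column 14
    nm <- ifelse(nchar(a$name) >= 4L, substr(a$name, 1L, 4L),
                 sprintf(" %-3s", a$name))
    writeLines(sprintf("ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                       a$serial %% 100000L, nm, substr(a$resname, 1L, 4L),
                       substr(a$chain, 1L, 1L), a$resno %% 10000L,
                       a$x, a$y, a$z), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

as_structure_models <- function(ensemble) {
  if (inherits(ensemble, "conformer_ensemble")) {
    return(lapply(seq_len(n_frames(ensemble)), function(f) {
      a <- ensemble$atoms
      a$x <- ensemble$coords[, 1L, f]
      a$y <- ensemble$coords[, 2L, f]
      a$z <- ensemble$coords[, 3L, f]
      structure(list(model_index = f, atoms = a, source = "ensemble"),
                class = "structure_model")
    }))
  }
  if (inherits(ensemble, "structure_model")) return(list(ensemble))
  stopifnot(is.list(ensemble), all(vapply(ensemble, inherits, TRUE,
                                          "structure_model")))
  ensemble
}

#' Convert structure models to a conformer ensemble
#'
#' Stacks a list of models sharing one topology (same atoms in the same
#' order) into the package's internal multi-frame container used by the
#' H-bond and conformation analyses.
#'
#' @param models list of `structure_model` objects, e.g. from
#'   [read_pdb_models()].
#' @return a `conformer_ensemble`: list with `atoms` (topology data frame)
#'   and `coords` (atoms x 3 x frames array).
#' @export
models_to_ensemble <- function(models) {
  models <- as_structure_models(models)
  ref <- models[[1L]]$atoms
  coords <- array(NA_real_, dim = c(nrow(ref), 3L, length(models)))
  for (f in seq_along(models)) {
    a <- models[[f]]$atoms
    if (nrow(a) != nrow(ref) || !all(a$name == ref$name & a$resno == ref$resno))
      stop("models do not share a topology (model ", f, " differs)")
    coords[, , f] <- cbind(a$x, a$y, a$z)
  }
  topo <- ref[, c("serial", "name", "resname", "resno", "chain")]
  structure(list(atoms = topo, coords = coords), class = "conformer_ensemble")
}

n_frames <- function(ensemble) dim(ensemble$coords)[3L]

#' Construct a conformer ensemble from an atom table and coordinates
#'
#' @param atoms data frame with columns `name`, `resname`, `resno` and
#'   optionally `serial`, `chain`.
#' @param coords numeric array of dimension (atoms, 3, frames), or an
#'   (atoms x 3) matrix for a single frame.
#' @return a `conformer_ensemble`.
#' @export
conformer_ensemble <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "resname", "resno") %in% names(atoms)))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[1L] == nrow(atoms),
            dim(coords)[2L] == 3L, all(is.finite(coords)))
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$chain)) atoms$chain <- "A"
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) in topology: ",
         key[anyDuplicated(key)])
  structure(list(atoms = atoms, coords = coords),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("Conformer ensemble: %d atoms, %d residues, %d frames\n",
              nrow(x$atoms), length(unique(x$atoms$resno)), n_frames(x)))
  invisible(x)
}

#' Measure an interatomic distance in one structure model
#'
#' Euclidean distance between two uniquely selected atoms, reported both at
#' full precision and rounded half-up to one decimal (the precision at which
#' such distances are conventionally quoted). Ambiguous or empty selections
#' are rejected with the list of candidates.
#'
#' @param model a `structure_model`.
#' @param sel_a,sel_b selector lists with any of `resno`, `name`, `chain`,
#'   `resname`; each must resolve to exactly one atom.
#' @return list with `distance` (full precision), `rounded` (1 decimal,
#'   half-up) and the two resolved atom rows.
#' @examples
#' \dontrun{
#' m <- read_pdb_models("ensemble.pdb")[[1]]
#' measure_distance(m, list(resno = 22, name = "OG"),
#'                  list(resno = 19, name = "O"))
#' }
#' @export
measure_distance <- function(model, sel_a, sel_b) {
  stopifnot(inherits(model, "structure_model"))
  a <- select_atom(model$atoms, sel_a)
  b <- select_atom(model$atoms, sel_b)
  d <- sqrt(sum((c(a$x, a$y, a$z) - c(b$x, b$y, b$z))^2))
  list(distance = d, rounded = round_half_up(d, 1L), atom_a = a, atom_b = b)
}

select_atom <- function(atoms, sel) {
  stopifnot(is.list(sel))
  keep <- rep(TRUE, nrow(atoms))
  for (field in intersect(names(sel), c("resno", "name", "chain", "resname")))
    keep <- keep & atoms[[field]] == sel[[field]]
  hits <- atoms[keep, , drop = FALSE]
  if (nrow(hits) == 0L)
    stop("selector matched no atom: ", deparse1(sel))
  if (nrow(hits) > 1L)
    stop("ambiguous selector ", deparse1(sel), "; candidates: ",
         paste(sprintf("%s%d/%s", hits$resname, hits$resno, hits$name),
               collapse = ", "))
  hits
}

# round-half-up (round() rounds half to even, which would print 2.75 A as 2.7)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
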