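# Coordinate and tabular input handling. Units throughout the package:
# coordinates in Angstrom, time in ns, energy in kcal/mol, angles in degrees.

#' Construct a structure object
#'
#' A `structure_model` holds an ordered atom table with chain/residue identity,
#' coordinates in Angstrom, and optional per-atom mass (Da), partial charge (e)
#' and Lennard-Jones parameters (epsilon in kcal/mol, Rmin in Angstrom).
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `chain`,
#'   `resno`, `resname`, `x`, `y`, `z`; optional `mass`, `charge`,
#'   `lj_epsilon`, `lj_rmin`, `is_hetero`.
#' @param title optional title string.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, title = "") {
  req <- c("serial", "name", "element", "chain", "resno", "resname", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("mass", "charge", "lj_epsilon", "lj_rmin")) {
    if (is.null(atoms[[opt]])) atoms[[opt]] <- NA_real_
  }
  if (is.null(atoms$is_hetero)) atoms$is_hetero <- FALSE
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 0 && !all(is.finite(xyz))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(!is.na(atoms$mass) & atoms$mass <= 0)) {
    stop("atom masses must be positive where present")
  }
  obj <- list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE), title = title)
  class(obj) <- "structure_model"
  obj
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %d atoms, %d chains, %d residues%s\n",
    nrow(x$atoms), length(unique(x$atoms$chain)), count_residues(x),
    if (nzchar(x$title)) paste0(" - ", x$title) else ""
  ))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a `structure_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinate matrix of a structure
#' @param structure a `structure_model`.
#' @return numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @export
coords <- function(structure) {
  unname(as.matrix(structure$atoms[, c("x", "y", "z")]))
}

#' Replace the coordinates of a structure
#' @param structure a `structure_model`.
#' @param xyz numeric n x 3 matrix (Angstrom).
#' @return the structure with updated coordinates.
#' @export
set_coords <- function(structure, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(structure) || ncol(xyz) != 3) {
    stop("coordinate matrix must be n_atoms x 3")
  }
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

# Resolve per-atom masses: explicit mass wins, otherwise the element symbol is
# mapped through bio3d's element table. Unknown elements are an error rather
# than a guessed mass.
atom_masses <- function(structure, indices = NULL) {
  at <- structure$atoms
  if (!is.null(indices)) at <- at[indices, , drop = FALSE]
  m <- at$mass
  need <- which(is.na(m))
  if (length(need) > 0) {
    key <- at$element[need]
    blank <- !nzchar(trimws(key)) | is.na(key)
    key[blank] <- at$name[need][blank]
    looked <- tryCatch(
      suppressWarnings(bio3d::atom2mass(key, rescue = FALSE)),
      error = function(e) stop(
        "cannot resolve a mass for atom(s) with element/name: ",
        paste(unique(key), collapse = ", "), call. = FALSE
      )
    )
    if (any(is.na(looked))) {
      stop("cannot resolve a mass for element(s): ",
           paste(unique(key[is.na(looked)]), collapse = ", "))
    }
    m[need] <- looked
  }
  m
}

solvent_resnames <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "NA", "CL", "K", "MG")

gz_to_text <- function(path) {
  if (!grepl("\\.gz$", path)) return(path)
  tmp <- tempfile(fileext = ".txt")
  con <- gzfile(path, "rt")
  on.exit(close(con))
  writeLines(readLines(con), tmp)
  tmp
}

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records (fixed-column PDB v3.3, via bio3d). Elements are
#' taken from columns 77-78 when present, otherwise inferred from the atom
#' name. Alternate locations are resolved by keeping the highest-occupancy
#' conformer (ties broken alphabetically by altloc id) or by raising an error,
#' per `altloc_policy`. Waters and other solvent are retained and flagged;
#' `strip_solvent = TRUE` removes them at read time. Gzip-compressed files
#' (`.gz`) are accepted.
#'
#' @param path path to a PDB file (optionally gzipped).
#' @param altloc_policy `"keep-first"` (default) or `"error"`.
#' @param strip_solvent drop water/ion residues (default `FALSE`).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, altloc_policy = c("keep-first", "error"),
                           strip_solvent = FALSE) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(gz_to_text(path), multi = FALSE, rm.alt = FALSE,
                    verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  st <- atoms_from_bio3d(at, altloc_policy = altloc_policy, path = path)
  if (strip_solvent) {
    keep <- !(st$atoms$resname %in% solvent_resnames)
    st$atoms <- st$atoms[keep, , drop = FALSE]
    rownames(st$atoms) <- NULL
  }
  st$title <- basename(path)
  st
}

atoms_from_bio3d <- function(at, altloc_policy = "keep-first", path = "") {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    if (altloc_policy == "error") {
      stop("alternate locations present in '", path,
           "' and altloc_policy = 'error'")
    }
    key <- paste(at$chain, at$resno, at$elety, sep = "\r")
    occ <- at$o
    occ[is.na(occ)] <- 1
    ord <- order(key, -occ, alt)
    at2 <- at[ord, , drop = FALSE]
    at2 <- at2[!duplicated(paste(at2$chain, at2$resno, at2$elety, sep = "\r")), ,
               drop = FALSE]
    at <- at2[order(as.integer(rownames(at2))), , drop = FALSE]
  }
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate atom after altloc resolution: ",
         gsub("\r", "/", dup))
  }
  ele <- at$elesy
  ele[is.na(ele)] <- ""
  ele <- trimws(ele)
  need <- !nzchar(ele)
  if (any(need)) {
    ele[need] <- tryCatch(
      suppressWarnings(bio3d::atom2ele(at$elety[need], rescue = FALSE)),
      error = function(e) stop(
        "cannot infer element for atom name(s): ",
        paste(unique(at$elety[need]), collapse = ", "), call. = FALSE)
    )
  }
  chain <- at$chain
  chain[is.na(chain)] <- " "
  structure_model(
    data.frame(
      serial = at$eleno, name = at$elety, element = ele,
      chain = chain, resno = at$resno, resname = at$resid,
      x = at$x, y = at$y, z = at$z,
      is_hetero = at$type == "HETATM",
      stringsAsFactors = FALSE
    )
  )
}

bio3d_from_structure <- function(structure) {
  at <- structure$atoms
  n <- nrow(at)
  bat <- data.frame(
    type = ifelse(at$is_hetero, "HETATM", "ATOM"),
    eleno = at$serial, elety = at$name, alt = "",
    resid = at$resname, chain = at$chain, resno = at$resno, insert = "",
    x = at$x, y = at$y, z = at$z, o = 1, b = 0, segid = "",
    elesy = at$element, charge = "", stringsAsFactors = FALSE
  )
  xyz <- matrix(as.numeric(t(as.matrix(at[, c("x", "y", "z")]))), nrow = 1)
  pdb <- list(atom = bat, xyz = xyz)
  class(pdb) <- "pdb"
  pdb
}

#' Write a structure to a PDB file
#' @param structure a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  pdb <- bio3d_from_structure(structure)
  bio3d::write.pdb(pdb, file = path)
  invisible(path)
}

#' Construct a trajectory object
#'
#' Ordered frames of one structure's coordinates with per-frame timestamps in
#' ns. All frames must share the reference structure's atom count, and
#' timestamps must be strictly increasing.
#'
#' @param structure reference `structure_model` (topology and frame 1 layout).
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param times_ns numeric vector of frame times (ns), strictly increasing.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(structure, frames, times_ns) {
  n <- n_atoms(structure)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3) {
      stop("frame ", k, " is not an n_atoms x 3 matrix (expected ", n, " atoms)")
    }
  }
  if (length(times_ns) != length(frames)) {
    stop("times_ns length must equal frame count")
  }
  if (length(times_ns) > 1 && any(diff(times_ns) <= 0)) {
    stop("times_ns must be strictly increasing")
  }
  obj <- list(structure = structure, frames = frames, times_ns = as.numeric(times_ns))
  class(obj) <- "md_trajectory"
  obj
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, %.3g-%.3g ns\n",
              length(x$frames), n_atoms(x$structure),
              min(x$times_ns), max(x$times_ns)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Read a multi-model PDB trajectory
#'
#' Frames are MODEL/ENDMDL blocks of a PDB file; atom order must be identical
#' across models. Timestamps come either from a uniform `dt_ns` (frame k gets
#' time (k-1)*dt) or an explicit `times_ns` vector.
#'
#' @param path multi-model PDB file (optionally gzipped).
#' @param dt_ns uniform frame spacing in ns.
#' @param times_ns explicit per-frame times in ns (overrides `dt_ns`).
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(path, dt_ns = NULL, times_ns = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- gz_to_text(path)
  lines <- readLines(txt)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_id <- cumsum(grepl("^MODEL", lines))
  if (max(model_id) == 0) model_id[] <- 1L
  counts <- tapply(is_atom, model_id, sum)
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("no coordinate records in '", path, "'")
  if (length(unique(counts)) > 1) {
    bad <- which(counts != counts[[1]])[1]
    stop("atom-count mismatch between models: model ", names(counts)[bad],
         " has ", counts[[bad]], " atoms, model 1 has ", counts[[1]])
  }
  pdb <- bio3d::read.pdb(txt, multi = TRUE, verbose = FALSE)
  st <- atoms_from_bio3d(pdb$atom, path = path)
  nf <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nf), function(k) {
    matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
  })
  if (is.null(times_ns)) {
    if (is.null(dt_ns)) dt_ns <- 1
    times_ns <- (seq_len(nf) - 1) * dt_ns
  }
  st$title <- basename(path)
  md_trajectory(st, frames, times_ns)
}

#' Write a trajectory as multi-model PDB
#' @param trajectory an `md_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  pdb <- bio3d_from_structure(trajectory$structure)
  xyz <- do.call(rbind, lapply(trajectory$frames, function(f) as.numeric(t(f))))
  bio3d::write.pdb(pdb, file = path, xyz = xyz)
  invisible(path)
}

#' Define a named domain as chain/residue-range members
#'
#' Residue ranges use author (1-based) PDB numbering and are inclusive on both
#' ends. A member is one chain plus a residue range with an optional atom-name
#' filter (e.g. `"CA"`).
#'
#' @param name domain label (e.g. `"constant"`, `"variable"`, `"tm_helix_1"`).
#' @param chain character vector of chain ids, one per member.
#' @param from,to integer vectors of first/last residue numbers, per member.
#' @param atom_names optional atom-name filter applied to every member.
#' @return An object of class `domain_definition`.
#' @export
domain_definition <- function(name, chain, from, to, atom_names = NULL) {
  if (length(chain) != length(from) || length(from) != length(to)) {
    stop("chain, from, to must have equal lengths")
  }
  if (length(chain) == 0) stop("domain '", name, "' has no members")
  if (any(to < from)) stop("domain '", name, "' has an empty residue range")
  obj <- list(name = name,
              members = data.frame(chain = chain, from = as.integer(from),
                                   to = as.integer(to), stringsAsFactors = FALSE),
              atom_names = atom_names)
  class(obj) <- "domain_definition"
  obj
}

#' Select atoms from a structure
#'
#' Deterministic selection ordered by input atom order. Either pass a
#' [domain_definition()] or any combination of `chain`, residue range and
#' `name` filters. An empty result is an error, never a silent empty set.
#'
#' @param structure a `structure_model`.
#' @param domain a `domain_definition` (overrides the other filters).
#' @param chain chain id(s) to keep.
#' @param resno integer vector of residue numbers to keep (e.g. `1:213`).
#' @param name atom name(s) to keep (e.g. `"CA"`).
#' @param label selection label.
#' @return An object of class `atom_selection` with fields `label` and
#'   `indices` (ordered, unique, 1-based row indices into the atom table).
#' @export
select_atoms <- function(structure, domain = NULL, chain = NULL, resno = NULL,
                         name = NULL, label = NULL) {
  at <- structure$atoms
  if (!is.null(domain)) {
    stopifnot(inherits(domain, "domain_definition"))
    keep <- rep(FALSE, nrow(at))
    for (k in seq_len(nrow(domain$members))) {
      m <- domain$members[k, ]
      keep <- keep | (at$chain == m$chain & at$resno >= m$from & at$resno <= m$to)
    }
    if (!is.null(domain$atom_names)) keep <- keep & at$name %in% domain$atom_names
    if (is.null(label)) label <- domain$name
  } else {
    keep <- rep(TRUE, nrow(at))
    if (!is.null(chain)) keep <- keep & at$chain %in% chain
    if (!is.null(resno)) keep <- keep & at$resno %in% resno
    if (!is.null(name)) keep <- keep & at$name %in% name
    if (is.null(label)) {
      label <- paste(c(
        if (!is.null(chain)) paste0("chain ", paste(chain, collapse = ",")),
        if (!is.null(resno)) paste0("resno ", min(resno), "-", max(resno)),
        if (!is.null(name)) paste0("name ", paste(name, collapse = ","))
      ), collapse = " & ")
      if (!nzchar(label)) label <- "all"
    }
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    stop("empty selection: ", label)
  }
  obj <- list(label = label, indices = idx)
  class(obj) <- "atom_selection"
  obj
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

#' Count distinct residues in a structure
#'
#' Counts distinct (chain, residue number) pairs, excluding water/solvent and
#' hetero-flagged residues, as used for dummy-residue bookkeeping in bead
#' modelling.
#'
#' @param structure a `structure_model`.
#' @param chains optional chain ids to restrict to.
#' @return integer residue count.
#' @export
count_residues <- function(structure, chains = NULL) {
  at <- structure$atoms
  keep <- !(at$resname %in% solvent_resnames) & !at$is_hetero
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) return(0L)
  length(unique(paste(at$chain, at$resno, sep = "\r")))
}

#' Construct a per-frame interaction-energy series
#'
#' Stores per-frame electrostatic and van der Waals inter-group energies
#' (kcal/mol) plus the derived linear interaction energy
#' `e_lie = a_elec * e_elec + a_vdw * e_vdw`.
#'
#' @param times_ns frame times (ns).
#' @param e_elec,e_vdw per-frame energies (kcal/mol).
#' @param coeffs named LIE coefficients `c(elec = 0.5, vdw = 0.18)`.
#' @return data.frame of class `energy_series` with columns `time_ns`,
#'   `e_elec`, `e_vdw`, `e_lie`; coefficients stored in attribute `coeffs`.
#' @export
energy_series <- function(times_ns, e_elec, e_vdw,
                          coeffs = c(elec = 0.5, vdw = 0.18)) {
  if (length(times_ns) != length(e_elec) || length(e_elec) != length(e_vdw)) {
    stop("times_ns, e_elec, e_vdw must have equal lengths")
  }
  if (length(times_ns) == 0) stop("empty energy series")
  out <- data.frame(time_ns = as.numeric(times_ns),
                    e_elec = as.numeric(e_elec),
                    e_vdw = as.numeric(e_vdw))
  out$e_lie <- lie_energy(out$e_elec, out$e_vdw, coeffs)
  attr(out, "coeffs") <- coeffs
  class(out) <- c("energy_series", "data.frame")
  out
}

#' Read a per-frame energy table
#'
#' Delimited text (comma or whitespace, `#` comments) with columns `time_ns`,
#' `e_elec`, `e_vdw` in kcal/mol. Gzip input accepted.
#'
#' @param path input file.
#' @param coeffs LIE coefficients passed to [energy_series()].
#' @return An [energy_series()].
#' @export
read_energy_table <- function(path, coeffs = c(elec = 0.5, vdw = 0.18)) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- gz_to_text(path)
  first <- readLines(txt, n = 50)
  first <- first[!grepl("^\\s*#", first) & nzchar(trimws(first))]
  if (length(first) == 0) stop("empty energy table: ", path)
  sep <- if (grepl(",", first[1])) "," else ""
  tab <- utils::read.table(txt, header = TRUE, sep = sep, comment.char = "#",
                           strip.white = TRUE)
  need <- c("time_ns", "e_elec", "e_vdw")
  if (!all(need %in% names(tab))) {
    stop("energy table '", path, "' lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (nrow(tab) == 0) stop("energy table '", path, "' has a header but no rows")
  energy_series(tab$time_ns, tab$e_elec, tab$e_vdw, coeffs)
}

#' Write an energy series as CSV
#' @param series an `energy_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(series, path) {
  utils::write.csv(series[, c("time_ns", "e_elec", "e_vdw")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
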