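#' Molecular structure container
#'
#' A light container for point-atom structures: each atom carries a name, a
#' residue name and index, a chain identifier and a 3-D position in Angstrom.
#' Optional per-atom masses (Da) are used by centre-of-mass operations.
#' Covalent links recorded by [join_chains()] ride along as metadata so the
#' elastic-network model can bridge chains regardless of the distance cutoff.
#'
#' @param atoms data.frame with columns `atom_name`, `residue_name`,
#'   `residue_index`, `chain_id`, `x`, `y`, `z` and optionally `mass`.
#' @param links data.frame with columns `chain_a`, `residue_a`, `chain_b`,
#'   `residue_b`, or `NULL`.
#' @return an object of class `MolecularStructure`.
#' @export
molecular_structure <- function(atoms, links = NULL) {
  required <- c("atom_name", "residue_name", "residue_index", "chain_id",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  if (nrow(atoms) > 0) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz)))
      stop("non-finite coordinates in structure")
    key <- paste(atoms$chain_id, atoms$residue_index, atoms$atom_name)
    if (anyDuplicated(key))
      stop("duplicate (chain, residue, atom) triple: ",
           key[which(duplicated(key))[1]])
    for (ch in unique(atoms$chain_id)) {
      ri <- atoms$residue_index[atoms$chain_id == ch]
      if (is.unsorted(ri))
        stop("residue indices not non-decreasing within chain ", ch)
    }
  }
  if (is.null(links)) {
    links <- data.frame(chain_a = character(), residue_a = integer(),
                        chain_b = character(), residue_b = integer(),
                        stringsAsFactors = FALSE)
  }
  structure(list(atoms = atoms, links = links), class = "MolecularStructure")
}

#' @export
print.MolecularStructure <- function(x, ...) {
  cat(sprintf("MolecularStructure: %d atoms, %d chains, %d recorded links\n",
              nrow(x$atoms), length(unique(x$atoms$chain_id)),
              nrow(x$links)))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `MolecularStructure`.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Atom coordinates as an n x 3 matrix (Angstrom)
#' @param s a `MolecularStructure`.
#' @export
coords <- function(s) unname(as.matrix(s$atoms[, c("x", "y", "z")]))

#' Trajectory frames sharing one atom roster
#'
#' @param struct the `MolecularStructure` giving the atom roster (coordinates
#'   of the first frame).
#' @param frame_coords array of dim `c(n_atoms, 3, n_frames)`, Angstrom.
#' @param times_ps frame times in ps, strictly increasing; defaults to
#'   `(0, dt, 2 dt, ...)`.
#' @param dt_ps frame spacing used when `times_ps` is absent (default 1 ps).
#' @return an object of class `TrajectoryFrames`.
#' @export
trajectory_frames <- function(struct, frame_coords, times_ps = NULL,
                              dt_ps = 1) {
  stopifnot(inherits(struct, "MolecularStructure"))
  if (length(dim(frame_coords)) != 3 || dim(frame_coords)[2] != 3)
    stop("frame_coords must be an n_atoms x 3 x n_frames array")
  if (dim(frame_coords)[1] != n_atoms(struct))
    stop("frame atom count (", dim(frame_coords)[1],
         ") differs from roster (", n_atoms(struct), ")")
  n_frames <- dim(frame_coords)[3]
  if (is.null(times_ps)) times_ps <- (seq_len(n_frames) - 1) * dt_ps
  if (length(times_ps) != n_frames)
    stop("times_ps length must equal number of frames")
  if (n_frames > 1 && any(diff(times_ps) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(struct = struct, coords = frame_coords,
                 times_ps = as.numeric(times_ps)),
            class = "TrajectoryFrames")
}

#' @export
print.TrajectoryFrames <- function(x, ...) {
  cat(sprintf("TrajectoryFrames: %d frames x %d atoms, t = %g..%g ps\n",
              dim(x$coords)[3], dim(x$coords)[1],
              min(x$times_ps), max(x$times_ps)))
  invisible(x)
}

#' Number of frames
#' @param frames a `TrajectoryFrames`.
#' @export
n_frames <- function(frames) dim(frames$coords)[3]

# Validate raw PDB lines before handing the text to bio3d: numeric coordinate
# fields, no insertion codes, first altloc kept. Returns the cleaned lines.
validate_pdb_lines <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("empty input: no ATOM/HETATM records found")
  atom_lineno <- which(is_atom)
  keep <- rep(TRUE, length(atom_lineno))
  seen_altloc <- new.env(parent = emptyenv())
  for (j in seq_along(atom_lineno)) {
    i <- atom_lineno[j]
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM record (truncated) at line ", i)
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v))
        stop("malformed coordinate field at line ", i, ": '",
             substr(ln, fld[1], fld[2]), "'")
    }
    if (substr(ln, 27, 27) != " ")
      stop("insertion codes are not supported (line ", i, ")")
    altloc <- substr(ln, 17, 17)
    if (altloc != " ") {
      key <- paste(substr(ln, 22, 22), substr(ln, 23, 26),
                   substr(ln, 13, 16))
      first <- get0(key, envir = seen_altloc)
      if (is.null(first)) {
        assign(key, altloc, envir = seen_altloc)
      } else if (first != altloc) {
        keep[j] <- FALSE
      }
    }
  }
  drop <- atom_lineno[!keep]
  if (length(drop) > 0) lines <- lines[-drop]
  lines
}

#' Read a molecular structure (or trajectory) from PDB
#'
#' Accepts a file path or PDB text (a single string with newlines, or a
#' character vector of lines). Single-model files give a
#' [molecular_structure()]; files with more than one `MODEL` block give a
#' [trajectory_frames()] whose times default to `frame index * dt_ps`.
#' Parsing is delegated to \pkg{bio3d} after a validation pass that reports
#' malformed coordinate fields by line number, rejects insertion codes, and
#' keeps the first alternate location of each atom.
#'
#' @param source path to a PDB file, or PDB text.
#' @param dt_ps frame spacing in ps assigned to multi-model input.
#' @return a `MolecularStructure`, or a `TrajectoryFrames` when the file has
#'   more than one model.
#' @export
read_structure <- function(source, dt_ps = 1) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(source, collapse = "\n"), "\n",
                             fixed = TRUE))
  }
  lines <- validate_pdb_lines(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(atom_name = trimws(at$elety),
                      residue_name = trimws(at$resid),
                      residue_index = as.integer(at$resno),
                      chain_id = ifelse(is.na(at$chain), "A", at$chain),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  struct <- molecular_structure(atoms)
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models) || n_models <= 1) return(struct)
  arr <- array(NA_real_, dim = c(nrow(atoms), 3, n_models))
  for (m in seq_len(n_models))
    arr[, , m] <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  struct$atoms[, c("x", "y", "z")] <- arr[, , 1]
  trajectory_frames(struct, arr, dt_ps = dt_ps)
}

#' Write a structure to a PDB file
#'
#' @param s a `MolecularStructure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(s, file) {
  stopifnot(inherits(s, "MolecularStructure"))
  a <- s$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$residue_index, resid = a$residue_name,
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   chain = a$chain_id)
  invisible(file)
}

#' Read an XYZ trajectory
#'
#' Plain XYZ dialect: repeated blocks of an atom-count line, a comment line,
#' then `element x y z` rows (Angstrom). All frames must share one atom
#' roster; element symbols become atom names on a single chain.
#'
#' @param file path to an .xyz file.
#' @param dt_ps frame spacing in ps.
#' @return a `TrajectoryFrames` (single-frame files included, for uniformity).
#' @export
read_xyz <- function(file, dt_ps = 1) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!(seq_along(lines) > length(lines))]
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed atom-count line ", i, " in XYZ file")
    if (i + 1 + nat > length(lines)) stop("truncated XYZ frame at line ", i)
    block <- lines[(i + 2):(i + 1 + nat)]
    toks <- strsplit(trimws(block), "\\s+")
    el <- vapply(toks, `[[`, "", 1)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (!all(is.finite(xyz))) stop("malformed coordinate in XYZ frame at line ", i)
    frames[[length(frames) + 1]] <- list(el = el, xyz = xyz)
    i <- i + 2 + nat
  }
  if (length(frames) == 0) stop("empty input: no frames in XYZ file")
  el0 <- frames[[1]]$el
  arr <- array(NA_real_, dim = c(length(el0), 3, length(frames)))
  for (m in seq_along(frames)) {
    if (length(frames[[m]]$el) != length(el0))
      stop("frame ", m, " atom count differs from frame 1")
    arr[, , m] <- frames[[m]]$xyz
  }
  atoms <- data.frame(atom_name = el0, residue_name = "UNK",
                      residue_index = seq_along(el0), chain_id = "A",
                      x = arr[, 1, 1], y = arr[, 2, 1], z = arr[, 3, 1],
                      stringsAsFactors = FALSE)
  trajectory_frames(molecular_structure(atoms), arr, dt_ps = dt_ps)
}

#' Write trajectory frames to an XYZ file
#'
#' @param frames a `TrajectoryFrames`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(frames, file) {
  stopifnot(inherits(frames, "TrajectoryFrames"))
  el <- frames$struct$atoms$atom_name
  con <- file(file, "w")
  on.exit(close(con), add = TRUE)
  for (m in seq_len(n_frames(frames))) {
    writeLines(as.character(length(el)), con)
    writeLines(sprintf("frame %d t= %g ps", m, frames$times_ps[m]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", el,
                       frames$coords[, 1, m], frames$coords[, 2, m],
                       frames$coords[, 3, m]), con)
  }
  invisible(file)
}

#' Join two structures with recorded covalent links
#'
#' Merges the atoms of two structures and records a list of inter-chain
#' covalent links, e.g. the bond that splices a transmembrane-cytoplasmic
#' fragment onto an ectodomain. Links are metadata: the elastic-network
#' builder always bridges them with a spring even when the linked residues
#' lie beyond the distance cutoff.
#'
#' @param a,b `MolecularStructure` objects with disjoint chain ids.
#' @param links list of links, each `c(chain_a, residue_a, chain_b,
#'   residue_b)` with the first pair naming a residue of `a` and the second a
#'   residue of `b`; or a 4-column data.frame.
#' @return a `MolecularStructure` holding all atoms of both inputs plus the
#'   link metadata (links of the inputs are carried over).
#' @export
join_chains <- function(a, b, links = list()) {
  stopifnot(inherits(a, "MolecularStructure"), inherits(b, "MolecularStructure"))
  if (nrow(b$atoms) > 0 && nrow(a$atoms) > 0) {
    shared <- intersect(unique(a$atoms$chain_id), unique(b$atoms$chain_id))
    if (length(shared) > 0)
      stop("chain ids not disjoint (rename before joining): ",
           paste(shared, collapse = ", "))
  }
  if (is.data.frame(links)) {
    links <- lapply(seq_len(nrow(links)), function(i) unlist(links[i, ],
                                                             use.names = FALSE))
  }
  link_df <- data.frame(chain_a = character(), residue_a = integer(),
                        chain_b = character(), residue_b = integer(),
                        stringsAsFactors = FALSE)
  for (lk in links) {
    if (length(lk) != 4)
      stop("each link must be (chain_a, residue_a, chain_b, residue_b)")
    ca <- as.character(lk[1]); ra <- as.integer(lk[2])
    cb <- as.character(lk[3]); rb <- as.integer(lk[4])
    if (!any(a$atoms$chain_id == ca & a$atoms$residue_index == ra))
      stop("link residue not found in first structure: chain ", ca,
           " residue ", ra)
    if (!any(b$atoms$chain_id == cb & b$atoms$residue_index == rb))
      stop("link residue not found in second structure: chain ", cb,
           " residue ", rb)
    link_df <- rbind(link_df, data.frame(chain_a = ca, residue_a = ra,
                                         chain_b = cb, residue_b = rb,
                                         stringsAsFactors = FALSE))
  }
  merged <- rbind(a$atoms, b$atoms)
  out <- tryCatch(molecular_structure(merged),
                  error = function(e) stop("collision while merging: ",
                                           conditionMessage(e)))
  out$links <- rbind(a$links, b$links, link_df)
  out
}

#' Select atoms by name, chain and residue range
#'
#' Returns the (stable, ascending) indices of atoms matching every given
#' filter. A small text mini-language mirrors the filters for command-line
#' use: clauses joined by `and`, each one of `name N1 N2 ...`,
#' `chain C1 C2 ...` or `resid A:B` (also `A-B` or a plain list of indices),
#' e.g. `"chain A and name CA and resid 695:742"`.
#'
#' @param s a `MolecularStructure`.
#' @param name atom name(s) to keep, or `NULL`.
#' @param chain chain id(s) to keep, or `NULL`.
#' @param residue residue indices to keep (any integer vector), or `NULL`.
#' @param selection selection text in the mini-language, combined with the
#'   other filters.
#' @return integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(s, name = NULL, chain = NULL, residue = NULL,
                         selection = NULL) {
  stopifnot(inherits(s, "MolecularStructure"))
  if (!is.null(selection)) {
    parsed <- parse_selection(selection)
    if (!is.null(parsed$name)) name <- union(name, parsed$name)
    if (!is.null(parsed$chain)) chain <- union(chain, parsed$chain)
    if (!is.null(parsed$residue)) residue <- union(residue, parsed$residue)
  }
  keep <- rep(TRUE, nrow(s$atoms))
  if (!is.null(name)) keep <- keep & s$atoms$atom_name %in% name
  if (!is.null(chain)) keep <- keep & s$atoms$chain_id %in% chain
  if (!is.null(residue)) keep <- keep & s$atoms$residue_index %in% residue
  which(keep)
}

#' @rdname select_atoms
#' @export
parse_selection <- function(selection) {
  out <- list(name = NULL, chain = NULL, residue = NULL)
  clauses <- strsplit(selection, "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(toks) < 2)
      stop("cannot parse selection clause: '", cl, "'")
    kw <- tolower(toks[1]); args <- toks[-1]
    if (kw == "name") {
      out$name <- c(out$name, args)
    } else if (kw == "chain") {
      out$chain <- c(out$chain, args)
    } else if (kw %in% c("resid", "residue")) {
      for (a in args) {
        if (grepl("^[0-9]+[:-][0-9]+$", a)) {
          ab <- as.integer(strsplit(a, "[:-]")[[1]])
          out$residue <- c(out$residue, seq(ab[1], ab[2]))
        } else if (grepl("^[0-9]+$", a)) {
          out$residue <- c(out$residue, as.integer(a))
        } else stop("cannot parse residue token: '", a, "'")
      }
    } else stop("unknown selection keyword: '", kw, "'")
  }
  out
}
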