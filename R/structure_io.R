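# Structure reading and standard-format output.
#
# A BackboneChain is the package's central container for one polypeptide
# chain: per-residue N/CA/C(/O) coordinates, phi/psi dihedrals and
# chain-break flags.  Only backbone atoms are kept; no side chains, no
# repair, model 1 only unless asked otherwise.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

#' Construct a BackboneChain
#'
#' @param chain_id chain identifier.
#' @param residues data.frame with columns `seq_label` (author residue
#'   number plus insertion code), `resno`, `icode`, `aa` (one-letter code).
#' @param N,CA,C,O numeric matrices, one row per residue (O may contain
#'   `NA` rows).
#' @param break_cutoff peptide C(i-1)-N(i) distance (Angstrom) above which
#'   a chain break is flagged.
#' @return object of class `BackboneChain` with `phi`, `psi` (degrees,
#'   `NA` where undefined) and `chain_break_before` filled in.
#' @export
backbone_chain <- function(chain_id, residues, N, CA, C, O = NULL,
                           break_cutoff = 2.5) {
  n <- nrow(residues)
  stopifnot(nrow(N) == n, nrow(CA) == n, nrow(C) == n)
  if (is.null(O)) O <- matrix(NA_real_, n, 3)
  brk <- rep(FALSE, n)
  if (n > 1) {
    for (i in 2:n) {
      d <- sqrt(sum((C[i - 1, ] - N[i, ])^2))
      brk[i] <- !is.finite(d) || d > break_cutoff
    }
  }
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && !brk[i]) {
      phi[i] <- compute_dihedral(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    }
    if (i < n && !brk[i + 1]) {
      psi[i] <- compute_dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
    }
  }
  structure(
    list(chain_id = chain_id, residues = residues,
         N = N, CA = CA, C = C, O = O,
         phi = phi, psi = psi, chain_break_before = brk),
    class = "BackboneChain")
}

#' @export
print.BackboneChain <- function(x, ...) {
  cat(sprintf("BackboneChain %s: %d residues, %d chain break(s)\n",
              x$chain_id, nrow(x$residues), sum(x$chain_break_before)))
  invisible(x)
}

#' Number of residues in a BackboneChain
#' @param chain a `BackboneChain`.
#' @export
n_residues <- function(chain) nrow(chain$residues)

#' One-letter amino acid sequence of a chain
#' @param chain a `BackboneChain`.
#' @export
chain_sequence <- function(chain) paste(chain$residues$aa, collapse = "")

#' Read a protein chain from a PDB or mmCIF file
#'
#' Keeps backbone atoms of standard amino acids (HETATM records are used
#' only when the residue name is a standard amino acid, e.g. MSE).
#' Alternate locations are resolved to the highest-occupancy conformer,
#' ties going to the first in file order.  Residues lacking any of N, CA
#' or C are dropped with a warning.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`) file.
#' @param chain chain identifier; defaults to the first chain in the file.
#' @param model model number for multi-model files (default 1).
#' @param break_cutoff see [backbone_chain()].
#' @return a [backbone_chain()] object.
#' @export
read_structure <- function(path, chain = NULL, model = 1,
                           break_cutoff = 2.5) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif"
         else "pdb"
  atoms <- if (fmt == "cif") parse_mmcif_atoms(path) else
    parse_pdb_atoms(path)
  atoms <- atoms[atoms$model == model, , drop = FALSE]
  if (nrow(atoms) == 0) stop("no atoms in model ", model, " of ", path)
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (nrow(atoms) == 0) {
    stop("chain not found: '", chain, "' in ", path)
  }
  atoms_to_chain(atoms, chain, break_cutoff = break_cutoff, path = path)
}

parse_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model <- 1L
  cur_model <- 1L
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM", "MODEL ", "ENDMDL")
  lines <- lines[keep]
  rec <- rec[keep]
  out <- vector("list", length(lines))
  k <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (rec[i] == "MODEL ") {
      cur_model <- suppressWarnings(as.integer(substr(ln, 11, 14)))
      if (is.na(cur_model)) cur_model <- model + 1L
      next
    }
    if (rec[i] == "ENDMDL") next
    k <- k + 1L
    out[[k]] <- data.frame(
      het = rec[i] == "HETATM",
      name = trimws(substr(ln, 13, 16)),
      altloc = substr(ln, 17, 17),
      resname = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      resno = as.integer(substr(ln, 23, 26)),
      icode = sub(" ", "", substr(ln, 27, 27)),
      x = as.numeric(substr(ln, 31, 38)),
      y = as.numeric(substr(ln, 39, 46)),
      z = as.numeric(substr(ln, 47, 54)),
      occ = suppressWarnings(as.numeric(substr(ln, 55, 60))),
      model = cur_model,
      ord = k,
      stringsAsFactors = FALSE)
  }
  if (k == 0L) stop("no ATOM records in ", path)
  atoms <- do.call(rbind, out[seq_len(k)])
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms
}

# Minimal mmCIF atom_site reader: one loop_, whitespace-separated values,
# single/double-quoted tokens honoured.  Enough for coordinate files; not
# a general CIF parser.
parse_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0) stop("no _atom_site loop in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  start <- max(hdr_idx) + 1
  rows <- list()
  for (i in start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" ) next
    if (grepl("^(#|loop_|_|data_)", ln)) break
    rows[[length(rows) + 1]] <- cif_tokens(ln)
  }
  if (length(rows) == 0) stop("empty _atom_site loop in ", path)
  bad <- vapply(rows, length, 1L) != length(fields)
  if (any(bad)) stop("malformed _atom_site rows in ", path)
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- fields
  pick <- function(...) {
    for (f in c(...)) if (f %in% fields) return(tab[[f]])
    rep(NA_character_, nrow(tab))
  }
  undef <- function(v) ifelse(v %in% c(".", "?"), "", v)
  atoms <- data.frame(
    het = pick("group_PDB") == "HETATM",
    name = undef(pick("auth_atom_id", "label_atom_id")),
    altloc = undef(pick("label_alt_id")),
    resname = undef(pick("auth_comp_id", "label_comp_id")),
    chain = undef(pick("auth_asym_id", "label_asym_id")),
    resno = as.integer(undef(pick("auth_seq_id", "label_seq_id"))),
    icode = undef(pick("pdbx_PDB_ins_code")),
    x = as.numeric(pick("Cartn_x")),
    y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    occ = suppressWarnings(as.numeric(undef(pick("occupancy")))),
    model = suppressWarnings(as.integer(undef(pick("pdbx_PDB_model_num")))),
    stringsAsFactors = FALSE)
  atoms$altloc[atoms$altloc == ""] <- " "
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$model[is.na(atoms$model)] <- 1L
  atoms$ord <- seq_len(nrow(atoms))
  atoms
}

cif_tokens <- function(line) {
  toks <- character(0)
  i <- 1
  n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1
      while (j <= n && substr(line, j, j) != ch) j <- j + 1
      toks <- c(toks, substr(line, i + 1, j - 1))
      i <- j + 1
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1
      toks <- c(toks, substr(line, i, j - 1))
      i <- j
    }
  }
  toks
}

atoms_to_chain <- function(atoms, chain_id, break_cutoff = 2.5,
                           path = "<memory>") {
  atoms <- atoms[atoms$resname %in% names(AA3TO1), , drop = FALSE]
  if (nrow(atoms) == 0) {
    stop("empty chain: no standard amino acid residues in chain '",
         chain_id, "' of ", path)
  }
  key <- paste(atoms$resno, atoms$icode, sep = "|")
  ukeys <- unique(key)          # file order preserved
  n <- length(ukeys)
  want <- c("N", "CA", "C", "O")
  coord <- array(NA_real_, c(n, 3, 4), dimnames = list(NULL, NULL, want))
  meta <- data.frame(seq_label = character(n), resno = integer(n),
                     icode = character(n), aa = character(n),
                     stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    sub <- atoms[key == ukeys[r], , drop = FALSE]
    meta$resno[r] <- sub$resno[1]
    meta$icode[r] <- sub$icode[1]
    meta$seq_label[r] <- paste0(sub$resno[1], sub$icode[1])
    meta$aa[r] <- unname(AA3TO1[sub$resname[1]])
    for (a in want) {
      cand <- sub[sub$name == a, , drop = FALSE]
      if (nrow(cand) == 0) next
      # altloc: highest occupancy wins, ties broken by file order
      cand <- cand[order(-cand$occ, cand$ord), , drop = FALSE]
      coord[r, , a] <- c(cand$x[1], cand$y[1], cand$z[1])
    }
  }
  complete <- !apply(coord[, , c("N", "CA", "C"), drop = FALSE], 1,
                     function(m) any(is.na(m)))
  if (!all(complete)) {
    warning(sum(!complete), " residue(s) dropped from chain '", chain_id,
            "' (incomplete N/CA/C backbone): ",
            paste(meta$seq_label[!complete], collapse = ", "))
  }
  if (!any(complete)) {
    stop("empty chain: no residue with complete N/CA/C backbone in '",
         chain_id, "'")
  }
  idx <- which(complete)
  mat <- function(a) matrix(coord[idx, , a], ncol = 3)
  backbone_chain(chain_id, meta[idx, , drop = FALSE],
                 N = mat("N"), CA = mat("CA"), C = mat("C"), O = mat("O"),
                 break_cutoff = break_cutoff)
}

#' Write a BackboneChain as a PDB file
#'
#' Emits standard fixed-width ATOM records for N, CA, C and (when present)
#' O, ending with TER/END.
#'
#' @param chain a `BackboneChain`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(chain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  fmt <- "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f"
  for (i in seq_len(n_residues(chain))) {
    res3 <- names(AA3TO1)[match(chain$residues$aa[i], AA3TO1)]
    if (is.na(res3)) res3 <- "ALA"
    for (a in c("N", "CA", "C", "O")) {
      xyz <- chain[[a]][i, ]
      if (any(is.na(xyz))) next
      serial <- serial + 1L
      name4 <- sprintf(" %-3s", a)   # right-justified element start
      writeLines(sprintf(fmt, serial, name4, res3, chain$chain_id,
                         chain$residues$resno[i],
                         ifelse(chain$residues$icode[i] == "", " ",
                                chain$residues$icode[i]),
                         xyz[1], xyz[2], xyz[3], 1, 0), con)
    }
  }
  writeLines(c("TER", "END"), con)
  invisible(path)
}

#' Write PB sequences to a PB-FASTA file
#'
#' Lowercase letters a-p, `Z` for positions whose PB is undefined
#' (termini, chain breaks).  Headers carry the structure id, chain and
#' author residue range; sequences are wrapped at 60 characters.
#'
#' @param sequences list of [pb_sequence()] objects (may be empty).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pb_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sequences) {
    writeLines(sprintf(">%s", s$header), con)
    writeLines(wrap60(s$symbols), con)
  }
  invisible(path)
}

wrap60 <- function(s) {
  if (nchar(s) == 0) return(character(0))
  starts <- seq(1, nchar(s), by = 60)
  substring(s, starts, pmin(starts + 59, nchar(s)))
}

#' Read a (PB or amino acid) FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (length(lines) == 0) return(setNames(character(0), character(0)))
  if (!hdr[1]) stop("not a FASTA file: ", path)
  ids <- sub("^>", "", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")), "")
  # groups with a header but no sequence lines yield empty strings
  out <- setNames(rep("", length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  names(out) <- ids
  out
}

#' Write aligned sequences as FASTA
#'
#' @param seqs named character vector (equal lengths, `-` for gaps).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(sprintf(">%s", names(seqs)[i]), con)
    writeLines(wrap60(seqs[[i]]), con)
  }
  invisible(path)
}
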