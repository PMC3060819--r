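# The Protein Block (PB) structural alphabet: 16 five-residue backbone
# prototypes labelled a..p, each described by 8 dihedral angles
# (psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1), psi(i+1),
# phi(i+2)).  Assignment picks, for every residue with a complete
# 8-dihedral window, the prototype with the smallest RMSDA (root mean
# square deviation of wrapped angles).

PB_LABELS <- letters[1:16]
PB_UNDEF <- "Z"

.pb_cache <- new.env(parent = emptyenv())

#' The Protein Block alphabet
#'
#' Loads the 16 dihedral prototypes from the packaged table (or a
#' user-supplied file of the same layout: a `pb` label column plus eight
#' angle columns in window order).
#'
#' @param path optional prototype TSV; defaults to the table shipped with
#'   the package.
#' @return object of class `PBAlphabet`: a 16 x 8 numeric matrix
#'   `prototypes` with rownames a..p, plus the undefined symbol.
#' @export
pb_alphabet <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pb_cache$default)) return(.pb_cache$default)
    path <- system.file("extdata", "pb_prototypes.tsv",
                        package = "pbrefine", mustWork = TRUE)
    default <- TRUE
  } else default <- FALSE
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) != 16 || ncol(tab) != 9) {
    stop("prototype table must have 16 rows and 9 columns")
  }
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  if (!identical(sort(rownames(m)), PB_LABELS)) {
    stop("prototype labels must be exactly a..p")
  }
  m <- m[PB_LABELS, ]
  if (any(m <= -180 | m > 180)) stop("prototype angles outside (-180, 180]")
  obj <- structure(list(prototypes = m, undefined_symbol = PB_UNDEF),
                   class = "PBAlphabet")
  if (default) .pb_cache$default <- obj
  obj
}

#' Angular root mean square deviation between two dihedral windows
#'
#' @param window,prototype numeric 8-vectors of dihedrals in degrees; all
#'   values must be defined.
#' @return RMSDA in degrees: `sqrt(mean(d^2))` with `d` the wrapped
#'   angular difference in `[0, 180]`.
#' @export
rmsda <- function(window, prototype) {
  if (length(window) != length(prototype)) {
    stop("window and prototype must have equal length")
  }
  if (any(!is.finite(window)) || any(!is.finite(prototype))) {
    stop("undefined window: all dihedrals must be defined")
  }
  sqrt(mean(angle_diff(window, prototype)^2))
}

#' Construct a PBSequence
#'
#' @param symbols character string over `{a..p, Z}`.
#' @param chain the `BackboneChain` the string describes (optional).
#' @param header FASTA header text.
#' @return object of class `PBSequence`; `residue_index_map[i]` is the
#'   residue index (central residue of the 5-residue window) of symbol i.
#' @export
pb_sequence <- function(symbols, chain = NULL, header = NULL) {
  if (!grepl("^[a-pZ]*$", symbols)) {
    stop("PB string may contain only a..p and Z")
  }
  if (is.null(header)) {
    header <- if (is.null(chain)) "pb" else
      sprintf("%s %s-%s", chain$chain_id,
              chain$residues$seq_label[1],
              chain$residues$seq_label[n_residues(chain)])
  }
  structure(list(symbols = symbols,
                 residue_index_map = seq_len(nchar(symbols)),
                 chain = chain, header = header),
            class = "PBSequence")
}

#' @export
print.PBSequence <- function(x, ...) {
  cat(sprintf(">%s\n%s\n", x$header, x$symbols))
  invisible(x)
}

# 8-dihedral window for residue i, or NULL if undefined (termini, chain
# breaks inside the 5-residue window).
pb_window <- function(chain, i) {
  n <- n_residues(chain)
  if (i < 3 || i > n - 2) return(NULL)
  # no break between residues i-2 .. i+2
  if (any(chain$chain_break_before[(i - 1):(i + 2)])) return(NULL)
  w <- c(chain$psi[i - 2], chain$phi[i - 1], chain$psi[i - 1],
         chain$phi[i], chain$psi[i],
         chain$phi[i + 1], chain$psi[i + 1], chain$phi[i + 2])
  if (any(!is.finite(w))) return(NULL)
  w
}

#' Assign a Protein Block string to a backbone
#'
#' Each residue with a full 8-dihedral window (two residues of context on
#' both sides, no chain break inside the window) receives the label of the
#' prototype with minimal [rmsda()]; ties break to the lexicographically
#' smallest label.  All other positions are `Z`.
#'
#' @param chain a `BackboneChain`.
#' @param alphabet a `PBAlphabet` (default: packaged table).
#' @return a [pb_sequence()] of the same length as the chain.
#' @export
assign_pbs <- function(chain, alphabet = pb_alphabet()) {
  n <- n_residues(chain)
  sym <- rep(PB_UNDEF, n)
  proto <- alphabet$prototypes
  for (i in seq_len(n)) {
    w <- pb_window(chain, i)
    if (is.null(w)) next
    d <- sqrt(rowMeans(angle_diff(
      matrix(w, 16, 8, byrow = TRUE), proto)^2))
    sym[i] <- PB_LABELS[which.min(d)]   # which.min: first (smallest label)
  }
  pb_sequence(paste(sym, collapse = ""), chain = chain)
}
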