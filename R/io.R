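# Plain-text structure I/O. No installed R package reads PDB coordinate
# files or writes CA-only traces, so a minimal fixed-width reader/writer
# is provided; only CA atoms are consumed.

#' Read C-alpha atoms from a PDB file
#'
#' All-atom files are accepted; only ATOM records named CA are kept.
#'
#' @param path PDB file path.
#' @return data.frame with columns `chain`, `resid`, `x`, `y`, `z`,
#'   `model`.
#' @export
read_ca_pdb <- function(path) {
  lines <- readLines(path)
  model <- 1L
  out <- list()
  for (ln in lines) {
    if (startsWith(ln, "MODEL"))
      model <- as.integer(trimws(substr(ln, 11, 14)))
    else if (startsWith(ln, "ATOM") && trimws(substr(ln, 13, 16)) == "CA") {
      out[[length(out) + 1L]] <- data.frame(
        chain = trimws(substr(ln, 21, 22)),
        resid = as.integer(substr(ln, 23, 26)),
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)),
        model = model)
    }
  }
  if (length(out) == 0L) stop("no CA atoms found in ", path)
  do.call(rbind, out)
}

#' Write chain models as a CA-only PDB
#'
#' Residue numbers come from the register; unregistered beads get
#' occupancy 0 and sequential placeholder numbering after the last
#' registered residue.
#'
#' @param chains named list of `chain_model` (registered via
#'   [register_sequence()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chains_pdb <- function(chains, path) {
  lines <- character(0)
  serial <- 0L
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  for (cid in names(chains)) {
    ch <- chains[[cid]]
    if (ch$unassigned || nrow(ch$coords) == 0L) next
    real <- which(stats::complete.cases(ch$coords))
    xyz <- ch$coords[real, , drop = FALSE]
    reg <- if (is.null(ch$register)) rep(NA_integer_, nrow(xyz)) else ch$register
    occ <- ifelse(is.na(reg), 0, 1)
    filler <- max(c(0L, reg), na.rm = TRUE) + seq_len(sum(is.na(reg)))
    resnum <- reg
    resnum[is.na(reg)] <- filler
    res3 <- rep("ALA", nrow(xyz))
    if (!is.null(ch$sequence)) {
      aa <- strsplit(ch$sequence, "")[[1]]
      ok <- !is.na(reg)
      res3[ok] <- aa3[aa[reg[ok]]]
    }
    for (b in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
        serial %% 100000, res3[b], substr(cid, 1, 1), resnum[b] %% 10000,
        xyz[b, 1], xyz[b, 2], xyz[b, 3], occ[b]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA headers in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k)
    gsub("\\s", "", paste(lines[(hdr[k] + 1L):ends[k]], collapse = "")), "")
  names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs
}
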