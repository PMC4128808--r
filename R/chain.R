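#' Protein chain container
#'
#' Holds one polypeptide chain as an ordered residue list with heavy-atom
#' coordinates. Residue indexing is 1-based and sequential in chain order;
#' `resno` keeps the author numbering from the source file so that gaps
#' (missing residues) remain detectable during curation.
#'
#' @param chain_id Single chain identifier string.
#' @param res_type Character vector of three-letter residue codes, one per
#'   residue, in chain order.
#' @param atoms data.frame with columns `res` (1-based residue index),
#'   `x`, `y`, `z` (coordinates in Angstrom). Hydrogens are expected to be
#'   absent already.
#' @param resno Optional integer vector of author residue numbers
#'   (defaults to 1..n).
#' @return Object of class `protein_chain`.
#' @export
protein_chain <- function(chain_id, res_type, atoms, resno = NULL) {
  n <- length(res_type)
  if (n < 2L) stop("protein_chain needs at least 2 residues")
  stopifnot(is.data.frame(atoms), all(c("res", "x", "y", "z") %in% names(atoms)))
  atoms$res <- as.integer(atoms$res)
  if (any(atoms$res < 1L | atoms$res > n)) stop("atom residue index out of range")
  if (!all(seq_len(n) %in% atoms$res)) stop("every residue needs at least one atom")
  if (is.null(resno)) resno <- seq_len(n)
  structure(
    list(
      chain_id = as.character(chain_id),
      res_type = toupper(as.character(res_type)),
      atoms = atoms[c("res", "x", "y", "z")],
      resno = as.integer(resno)
    ),
    class = "protein_chain"
  )
}

#' @export
length.protein_chain <- function(x) length(x$res_type)

#' @export
print.protein_chain <- function(x, ...) {
  cat(
    "<protein_chain>", x$chain_id, ":", length(x$res_type), "residues,",
    nrow(x$atoms), "heavy atoms\n"
  )
  invisible(x)
}

chain_coords <- function(chain) {
  as.matrix(chain$atoms[c("x", "y", "z")])
}

#' Read one chain from a PDB file
#'
#' Parses ATOM records of a single-model PDB file with [bio3d::read.pdb()],
#' keeping heavy atoms only (hydrogens dropped) and the first alternate
#' location of each atom. Residues appear in file order.
#'
#' @param path Path to a PDB-format file.
#' @param chain_id Chain identifier to extract (default: first chain).
#' @return A [protein_chain]. Attribute `"partner_ids"` lists the other
#'   chain identifiers present in the file (used by [curate_chain()]).
#' @export
read_pdb_chain <- function(path, chain_id = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elesy <- toupper(ifelse(is.na(at$elesy) | at$elesy == "", substr(trimws(at$elety), 1L, 1L), at$elesy))
  at <- at[elesy != "H" & elesy != "D", , drop = FALSE]
  chains <- unique(at$chain)
  if (is.null(chain_id)) chain_id <- chains[1L]
  sel <- at[at$chain %in% chain_id, , drop = FALSE]
  if (nrow(sel) == 0L) stop("chain ", chain_id, " not found in ", path)
  key <- paste(sel$resno, sel$insert)
  res_index <- match(key, unique(key))
  first <- !duplicated(res_index)
  chain <- protein_chain(
    chain_id = chain_id,
    res_type = sel$resid[first],
    atoms = data.frame(res = res_index, x = sel$x, y = sel$y, z = sel$z),
    resno = sel$resno[first]
  )
  attr(chain, "partner_ids") <- setdiff(chains, chain_id)
  attr(chain, "source") <- path
  chain
}

#' Write a chain as a PDB file
#'
#' Emits CA/CB-style ATOM records through [bio3d::write.pdb()], so that
#' synthetic chains round-trip through the same parser as experimental
#' structures.
#'
#' @param chain A [protein_chain].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path) {
  xyz <- as.numeric(t(chain_coords(chain)))
  res <- chain$atoms$res
  # first atom of each residue labelled CA, remaining ones CB1, CB2, ...
  elety <- character(nrow(chain$atoms))
  for (r in unique(res)) {
    ii <- which(res == r)
    elety[ii] <- if (length(ii) == 1L) "CA" else c("CA", paste0("CB", seq_len(length(ii) - 1L)))
  }
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = chain$resno[res],
    resid = chain$res_type[res],
    chain = rep(chain$chain_id, nrow(chain$atoms)),
    elety = elety
  )
  invisible(path)
}

#' Curate a chain record for training-set inclusion
#'
#' Applies the dataset filters: chain length must lie in
#' `length_range` (default 46..500 residues), residue codes must all be
#' standard (no ASX/GLX/XLE/XAA/UNK), the author numbering must have no
#' gaps (missing residues), and at most `max_interchain` of the chain's
#' contacting residues may have a contact partner on another chain of the
#' same record. The inter-chain fraction is computed as
#' (#residues with >= 1 inter-chain contact) / (#residues with >= 1
#' contact of any kind), contacts defined exactly as in
#' [build_contact_map()] (sequence separation applies within-chain only).
#'
#' @param chain A [protein_chain].
#' @param partners Optional list of [protein_chain] partners from the same
#'   record (e.g. other chains of a complex).
#' @param length_range Integer length bounds, inclusive.
#' @param max_interchain Maximum tolerated inter-chain contact fraction.
#' @param cutoff,min_separation Contact definition, as in
#'   [build_contact_map()].
#' @return List with `accept` (logical) and `reason` (string, `"ok"` on
#'   acceptance; otherwise one of `"length"`, `"ambiguous-residues"`,
#'   `"missing-residues"`, `"inter-chain"`).
#' @export
curate_chain <- function(chain, partners = list(), length_range = c(46L, 500L),
                         max_interchain = 0.30, cutoff = 4.5, min_separation = 2L) {
  if (!inherits(chain, "protein_chain")) stop("not a protein_chain record")
  n <- length(chain$res_type)
  if (n < length_range[1L] || n > length_range[2L]) {
    return(list(accept = FALSE, reason = "length"))
  }
  if (any(chain$res_type %in% AMBIGUOUS_AA3) || !all(chain$res_type %in% AA3)) {
    return(list(accept = FALSE, reason = "ambiguous-residues"))
  }
  if (any(diff(chain$resno) > 1L)) {
    return(list(accept = FALSE, reason = "missing-residues"))
  }
  if (length(partners) > 0L) {
    frac <- interchain_fraction(chain, partners, cutoff, min_separation)
    if (is.finite(frac) && frac > max_interchain) {
      return(list(accept = FALSE, reason = "inter-chain"))
    }
  }
  list(accept = TRUE, reason = "ok")
}

# Fraction of this chain's contacting residues that touch another chain.
interchain_fraction <- function(chain, partners, cutoff = 4.5, min_separation = 2L) {
  n <- length(chain$res_type)
  coords <- chain_coords(chain)
  res <- chain$atoms$res
  for (k in seq_along(partners)) {
    pc <- chain_coords(partners[[k]])
    coords <- rbind(coords, pc)
    res <- c(res, partners[[k]]$atoms$res + n + 10000L * k)
  }
  # partner residues are offset far beyond n, so the sequence-separation
  # rule never suppresses an inter-chain pair
  edges <- residue_contacts(coords, res,
    cutoff = cutoff, min_separation = min_separation
  )
  if (nrow(edges) == 0L) {
    return(0)
  }
  mine <- edges$i <= n | edges$j <= n
  edges <- edges[mine, , drop = FALSE]
  touching <- unique(c(edges$i[edges$i <= n], edges$j[edges$j <= n]))
  inter <- edges[(edges$i <= n) != (edges$j <= n), , drop = FALSE]
  inter_res <- unique(c(inter$i[inter$i <= n], inter$j[inter$j <= n]))
  if (length(touching) == 0L) {
    return(0)
  }
  length(inter_res) / length(touching)
}
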