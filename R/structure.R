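# Structure model: atoms, residues, PDB IO, region selection, disulfides.
#
# A spies_structure is a light container over an atom table (one row per
# atom, altlocs already resolved to a single conformer) plus a derived
# residue table.  Residue identity is author numbering + insertion code so
# labels match crystallographic residue names.

STD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

# protonation-state variant names (Maestro/Amber/CHARMM) -> parent residue
AA_VARIANTS <- c(HID = "HIS", HIE = "HIS", HIP = "HIS", HSD = "HIS",
                 HSE = "HIS", HSP = "HIS", CYX = "CYS", CYM = "CYS",
                 ASH = "ASP", GLH = "GLU", LYN = "LYS", ARN = "ARG")

WATER_RESNAMES <- c("HOH", "WAT", "DOD")

AA_ONE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA_THREE <- stats::setNames(names(AA_ONE), AA_ONE)

canonical_resname <- function(resname) {
  out <- toupper(resname)
  hit <- out %in% names(AA_VARIANTS)
  out[hit] <- AA_VARIANTS[out[hit]]
  out
}

residue_kind <- function(resname, het) {
  cn <- canonical_resname(resname)
  ifelse(toupper(resname) %in% WATER_RESNAMES, "water",
         ifelse(cn %in% STD_AA, "amino_acid",
                ifelse(het, "ligand", "other")))
}

guess_element <- function(name) {
  core <- sub("^[0-9']+", "", toupper(name))
  el <- substr(core, 1L, 1L)
  el[el == "D"] <- "H"
  el[!nzchar(el)] <- "X"
  el
}

build_residue_table <- function(atoms) {
  key <- paste0(atoms$chain, "/", atoms$resseq, atoms$icode)
  first <- !duplicated(key)
  res <- data.frame(
    reskey  = key[first],
    chain   = atoms$chain[first],
    resseq  = atoms$resseq[first],
    icode   = atoms$icode[first],
    resname = atoms$resname[first],
    het     = atoms$het[first],
    stringsAsFactors = FALSE
  )
  res$kind <- residue_kind(res$resname, res$het)
  res$n_atoms <- as.integer(table(factor(key, levels = res$reskey)))
  rownames(res) <- NULL
  res
}

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `altloc`, `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`,
#'   `occupancy`, `het` (logical, HETATM record).  `element` may be `NA`
#'   and is then inferred from the atom name.
#' @param title optional title string.
#' @param chain_order optional explicit chain ordering; defaults to order
#'   of first appearance.
#' @return an object of class `spies_structure`.
#' @export
new_structure <- function(atoms, title = "", chain_order = NULL) {
  need <- c("serial", "name", "resname", "chain", "resseq", "icode",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atom table lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stopf("empty structure: no atoms")
  atoms$altloc    <- as.character(atoms$altloc %||% rep("", nrow(atoms)))
  atoms$occupancy <- as.numeric(atoms$occupancy %||% rep(1, nrow(atoms)))
  atoms$het       <- as.logical(atoms$het %||% rep(FALSE, nrow(atoms)))
  atoms$element   <- as.character(atoms$element %||% rep(NA, nrow(atoms)))
  bad_el <- is.na(atoms$element) | !nzchar(atoms$element)
  atoms$element[bad_el] <- guess_element(atoms$name[bad_el])
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$icode <- as.character(atoms$icode)
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$chain <- as.character(atoms$chain)
  atoms$chain[is.na(atoms$chain)] <- ""
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stopf("non-finite coordinates in atom table")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stopf("occupancy outside [0, 1]")
  atoms$is_hydrogen <- atoms$element %in% "H"
  atoms$reskey <- paste0(atoms$chain, "/", atoms$resseq, atoms$icode)
  rownames(atoms) <- NULL
  res <- build_residue_table(atoms)
  if (any(res$n_atoms == 0L)) stopf("residue with no atoms")
  chains <- unique(atoms$chain)
  if (is.null(chain_order)) chain_order <- chains
  if (!setequal(chain_order, chains))
    stopf("chain_order must cover exactly the chains present (%s)",
          paste(chains, collapse = ", "))
  out <- list(atoms = atoms, residues = res,
              chain_order = chain_order, title = title)
  class(out) <- "spies_structure"
  out
}

#' @export
print.spies_structure <- function(x, ...) {
  r <- x$residues
  cat(sprintf(
    "<spies_structure> %s\n  %d atoms, %d residues (%d amino acid, %d water, %d ligand/other) in chains: %s\n",
    if (nzchar(x$title)) x$title else "(untitled)",
    nrow(x$atoms), nrow(r),
    sum(r$kind == "amino_acid"), sum(r$kind == "water"),
    sum(!r$kind %in% c("amino_acid", "water")),
    paste(x$chain_order, collapse = ", ")))
  invisible(x)
}

#' Read a PDB file into a structure
#'
#' Waters are retained; per altloc group exactly one conformer is kept
#' according to `altloc_policy`; insertion codes are preserved.
#'
#' @param path path to a PDB-format file.
#' @param altloc_policy `"highest_occupancy"` (ties broken by altloc letter
#'   order) or `"first"` (first record in file order).
#' @return a [new_structure()] object.
#' @export
read_pdb <- function(path, altloc_policy = c("highest_occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stopf("cannot read '%s' as PDB: %s", path,
                              conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stopf("empty structure: '%s' has no atoms", path)
  atoms <- data.frame(
    serial    = a$eleno,
    name      = a$elety,
    element   = if ("elesy" %in% names(a)) a$elesy else NA_character_,
    altloc    = ifelse(is.na(a$alt), "", a$alt),
    resname   = a$resid,
    chain     = ifelse(is.na(a$chain), "", a$chain),
    resseq    = a$resno,
    icode     = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    het       = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- resolve_altlocs(atoms, altloc_policy)
  title <- basename(path)
  new_structure(atoms, title = title)
}

resolve_altlocs <- function(atoms, policy) {
  key <- paste0(atoms$chain, "/", atoms$resseq, atoms$icode, "/", atoms$name)
  if (!anyDuplicated(key)) return(atoms)
  keep <- vapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    if (policy == "first") return(idx[1L])
    occ <- atoms$occupancy[idx]
    best <- idx[occ == max(occ)]
    best[order(atoms$altloc[best])][1L]
  }, integer(1))
  atoms[sort(unname(keep)), , drop = FALSE]
}

#' Write a structure to a PDB file
#'
#' Round-trippable with [read_pdb()]: fields and coordinates (to 3
#' decimals) survive a write/read cycle.
#'
#' @param structure a `spies_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resseq, resid = a$resname,
    eleno = a$serial, elety = a$name,
    chain = ifelse(nzchar(a$chain), a$chain, NA),
    insert = ifelse(nzchar(a$icode), a$icode, NA),
    alt = ifelse(nzchar(a$altloc), a$altloc, NA),
    o = a$occupancy, b = rep(0, nrow(a)),
    elesy = a$element)
  invisible(path)
}

parse_keep <- function(keep) {
  if (is.data.frame(keep)) return(keep)
  if (is.character(keep)) {
    parts <- strsplit(keep, ",", fixed = TRUE)[[1]]
    keep <- lapply(parts, function(p) {
      bits <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
      if (length(bits) != 2L) stopf("cannot parse keep spec '%s'", p)
      rng <- trimws(bits[2])
      if (identical(tolower(rng), "all")) {
        list(chain = bits[1], from = -Inf, to = Inf)
      } else if (grepl("-", rng)) {
        ft <- as.numeric(strsplit(rng, "-", fixed = TRUE)[[1]])
        list(chain = bits[1], from = ft[1], to = ft[2])
      } else {
        list(chain = bits[1], from = as.numeric(rng), to = as.numeric(rng))
      }
    })
  }
  data.frame(
    chain = vapply(keep, function(k) k$chain, character(1)),
    from  = vapply(keep, function(k) k$from %||% -Inf, numeric(1)),
    to    = vapply(keep, function(k) k$to %||% Inf, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Subset a structure to selected chains/residue ranges
#'
#' @param structure a `spies_structure`.
#' @param keep selection: a string like `"A:1-120,B:all"`, a list of
#'   `list(chain=, from=, to=)`, or a data.frame with those columns.
#' @param waters_within if non-`NULL`, additionally retain water residues
#'   whose nearest atom lies within this radius (Angstrom) of any kept
#'   non-water atom.
#' @return a `spies_structure` containing exactly the selected residues
#'   (plus qualifying waters).
#' @export
select_region <- function(structure, keep, waters_within = NULL) {
  spec <- parse_keep(keep)
  res <- structure$residues
  bad <- setdiff(spec$chain, res$chain)
  if (length(bad)) stopf("chain(s) not in structure: %s",
                         paste(bad, collapse = ", "))
  sel <- rep(FALSE, nrow(res))
  for (i in seq_len(nrow(spec))) {
    sel <- sel | (res$chain == spec$chain[i] &
                  res$resseq >= spec$from[i] & res$resseq <= spec$to[i])
  }
  if (!is.null(waters_within)) {
    stopifnot(waters_within > 0)
    kept_atoms <- structure$atoms[structure$atoms$reskey %in%
                                    res$reskey[sel & res$kind != "water"], ]
    if (nrow(kept_atoms)) {
      ka <- as.matrix(kept_atoms[, c("x", "y", "z")])
      wat <- which(res$kind == "water" & !sel)
      for (w in wat) {
        wa <- structure$atoms[structure$atoms$reskey == res$reskey[w],
                              c("x", "y", "z")]
        if (cross_min_dist(as.matrix(wa), ka) <= waters_within) sel[w] <- TRUE
      }
    }
  }
  if (!any(sel)) stopf("empty selection")
  atoms <- structure$atoms[structure$atoms$reskey %in% res$reskey[sel], ]
  new_structure(atoms, title = structure$title)
}

#' Detect disulfide bridges by SG-SG distance
#'
#' Cysteine pairs are resolved greedily by ascending SG-SG distance so each
#' cysteine joins at most one bridge.
#'
#' @param structure a `spies_structure`.
#' @param sg_cutoff detection cutoff in Angstrom (default 2.5; a covalent
#'   S-S bond is about 2.05).
#' @return data.frame with columns `cys_a`, `cys_b` (residue keys,
#'   `cys_a < cys_b` lexicographically) and `sg_distance`.
#' @export
detect_disulfides <- function(structure, sg_cutoff = 2.5) {
  stopifnot(sg_cutoff > 0)
  res <- structure$residues
  cys <- res$reskey[canonical_resname(res$resname) == "CYS" &
                    res$kind == "amino_acid"]
  empty <- data.frame(cys_a = character(), cys_b = character(),
                      sg_distance = numeric(), stringsAsFactors = FALSE)
  if (length(cys) < 2L) return(empty)
  sg <- structure$atoms[structure$atoms$reskey %in% cys &
                        structure$atoms$name == "SG", ]
  missing_sg <- setdiff(cys, sg$reskey)
  if (length(missing_sg))
    warnf("CYS residue(s) lacking SG atom skipped: %s",
          paste(missing_sg, collapse = ", "))
  if (nrow(sg) < 2L) return(empty)
  co <- as.matrix(sg[, c("x", "y", "z")])
  d <- cross_dist(co, co)
  idx <- which(upper.tri(d) & d <= sg_cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cand <- data.frame(a = sg$reskey[idx[, 1]], b = sg$reskey[idx[, 2]],
                     dist = d[idx], stringsAsFactors = FALSE)
  cand <- cand[order(cand$dist, pmin(cand$a, cand$b), pmax(cand$a, cand$b)), ]
  used <- character()
  out <- empty
  for (i in seq_len(nrow(cand))) {
    if (cand$a[i] %in% used || cand$b[i] %in% used) next
    used <- c(used, cand$a[i], cand$b[i])
    pair <- sort(c(cand$a[i], cand$b[i]))
    out <- rbind(out, data.frame(cys_a = pair[1], cys_b = pair[2],
                                 sg_distance = cand$dist[i],
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Advisory structure validation ahead of fragmentation
#'
#' Reports residues missing hydrogens, unknown residue names, unresolved
#' altlocs, and chain breaks (consecutive amino acids with a Calpha-Calpha
#' distance above `ca_break`).  Purely advisory; never mutates.
#'
#' @param structure a `spies_structure`.
#' @param ca_break chain-break threshold in Angstrom (default 4.5).
#' @return data.frame with columns `reskey`, `resname`, `issue`, `detail`.
#' @export
validate_for_fmo <- function(structure, ca_break = 4.5) {
  res <- structure$residues
  atoms <- structure$atoms
  issues <- list()
  add <- function(reskey, resname, issue, detail = "") {
    issues[[length(issues) + 1L]] <<- data.frame(
      reskey = reskey, resname = resname, issue = issue, detail = detail,
      stringsAsFactors = FALSE)
  }
  # hydrogens present?
  h_per_res <- tapply(atoms$is_hydrogen, atoms$reskey, any)
  for (i in which(res$kind == "amino_acid")) {
    if (!isTRUE(h_per_res[[res$reskey[i]]]))
      add(res$reskey[i], res$resname[i], "no_hydrogens")
  }
  # unknown residue names
  for (i in which(res$kind == "other")) {
    add(res$reskey[i], res$resname[i], "unknown_residue",
        "not a standard amino acid, water, or HETATM ligand")
  }
  # unresolved altlocs: duplicate atom name within a residue
  key <- paste0(atoms$reskey, "/", atoms$name)
  dup <- unique(atoms$reskey[duplicated(key)])
  for (k in dup) {
    add(k, res$resname[match(k, res$reskey)], "unresolved_altloc")
  }
  # chain breaks
  for (ch in structure$chain_order) {
    aa <- which(res$chain == ch & res$kind == "amino_acid")
    if (length(aa) < 2L) next
    ca <- merge(data.frame(reskey = res$reskey[aa], ord = seq_along(aa),
                           stringsAsFactors = FALSE),
                atoms[atoms$name == "CA", c("reskey", "x", "y", "z")],
                by = "reskey", all.x = TRUE)
    ca <- ca[order(ca$ord), ]
    for (j in seq_len(nrow(ca) - 1L)) {
      if (is.na(ca$x[j]) || is.na(ca$x[j + 1L])) next
      d <- sqrt(sum((unlist(ca[j, c("x", "y", "z")]) -
                     unlist(ca[j + 1L, c("x", "y", "z")]))^2))
      if (d > ca_break)
        add(ca$reskey[j + 1L], res$resname[match(ca$reskey[j + 1L], res$reskey)],
            "chain_break", sprintf("Calpha-Calpha %.2f A to previous residue", d))
    }
  }
  if (length(issues) == 0L)
    return(data.frame(reskey = character(), resname = character(),
                      issue = character(), detail = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
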