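# Residue-based FMO fragmentation (one fragment per residue, HOP scheme).
#
# Backbone detachment is at the Calpha-C(carbonyl) sp3 bond: for every
# non-C-terminal residue i the carbonyl C and O atoms are members of
# fragment i+1, so a main-chain C=O hydrogen bond is attributed to the next
# residue's fragment.  Each water and each ligand residue is one fragment;
# the two cysteines of a disulfide bridge may be merged into one fragment.

#' Build a fragmentation plan for a structure
#'
#' One fragment per residue (amino acid, water, or ligand) with the
#' carbonyl-shift rule applied along each chain; optionally merges
#' disulfide-bonded cysteine pairs into single fragments.  Formal charges
#' are assigned from the hydrogen atoms present (see
#' [assign_formal_charges()]).
#'
#' @param structure a `spies_structure`.
#' @param merge_disulfides merge SG-bonded CYS pairs into one fragment.
#' @param sg_cutoff SG-SG disulfide detection cutoff, Angstrom.
#' @param ligand_charges named numeric vector of formal charges for ligand
#'   residues, keyed by residue name or residue key (default 0).
#' @param treat_as_ligand residue names of non-standard ATOM residues to
#'   fragment as ligands instead of raising an error.
#' @param notation optional label notation (see [fragment_label()]).
#' @return an object of class `spies_plan`: list with `fragments`
#'   (data.frame: index, label, kind, chain, resseq, charge, n_atoms,
#'   reskeys), `assignment` (data.frame: serial, fragment), `detached`
#'   (data.frame: bda_serial, baa_serial, owner_fragment), `total_charge`,
#'   `n_fragments`.
#' @export
build_fragmentation <- function(structure, merge_disulfides = TRUE,
                                sg_cutoff = 2.5, ligand_charges = NULL,
                                treat_as_ligand = character(),
                                notation = NULL) {
  res <- structure$residues
  atoms <- structure$atoms
  res$kind[res$kind == "other" &
             toupper(res$resname) %in% toupper(treat_as_ligand)] <- "ligand"
  if (any(res$kind == "other"))
    stopf("non-standard residue(s) not declared as ligand: %s",
          paste(res$reskey[res$kind == "other"], collapse = ", "))

  frag_of_atom <- match(atoms$reskey, res$reskey)   # start: fragment == residue
  detached <- data.frame(bda_serial = integer(), baa_serial = integer(),
                         owner_fragment = integer())

  for (ch in structure$chain_order) {
    aa <- which(res$chain == ch & res$kind == "amino_acid")
    if (length(aa) == 0L) next
    # every amino-acid residue must expose CA and C for the HOP scheme
    for (r in aa) {
      sel <- atoms$reskey == res$reskey[r]
      if (!any(sel & atoms$name == "CA") || !any(sel & atoms$name == "C"))
        stopf("cannot fragment residue %s (%s): missing CA or C atom",
              res$reskey[r], res$resname[r])
    }
    if (length(aa) < 2L) next
    for (k in seq_len(length(aa) - 1L)) {
      r <- aa[k]; nxt <- aa[k + 1L]
      sel <- atoms$reskey == res$reskey[r]
      co <- sel & atoms$name %in% c("C", "O")
      frag_of_atom[co] <- nxt
      ca_i <- which(sel & atoms$name == "CA")[1L]
      c_i <- which(sel & atoms$name == "C")[1L]
      bond <- sqrt(sum((unlist(atoms[ca_i, c("x", "y", "z")]) -
                        unlist(atoms[c_i, c("x", "y", "z")]))^2))
      if (bond >= 1.8)
        stopf("residue %s: CA-C distance %.2f A is not a covalent bond",
              res$reskey[r], bond)
      detached <- rbind(detached, data.frame(
        bda_serial = atoms$serial[ca_i], baa_serial = atoms$serial[c_i],
        owner_fragment = r))
    }
  }

  # disulfide merging: union the two CYS fragments, keep the lower index
  merged_pairs <- data.frame(cys_a = character(), cys_b = character(),
                             sg_distance = numeric())
  frag_sources <- as.list(seq_len(nrow(res)))   # residue indices per fragment id
  if (merge_disulfides) {
    merged_pairs <- detect_disulfides(structure, sg_cutoff)
    for (i in seq_len(nrow(merged_pairs))) {
      fa <- match(merged_pairs$cys_a[i], res$reskey)
      fb <- match(merged_pairs$cys_b[i], res$reskey)
      lo <- min(fa, fb); hi <- max(fa, fb)
      frag_of_atom[frag_of_atom == hi] <- lo
      detached$owner_fragment[detached$owner_fragment == hi] <- lo
      frag_sources[[lo]] <- sort(c(frag_sources[[lo]], frag_sources[[hi]]))
      frag_sources[[hi]] <- integer()
    }
  }

  live <- which(lengths(frag_sources) > 0L)
  remap <- integer(nrow(res)); remap[live] <- seq_along(live)
  frag_of_atom <- remap[frag_of_atom]
  detached$owner_fragment <- remap[detached$owner_fragment]
  frag_sources <- frag_sources[live]

  frag <- data.frame(
    index = seq_along(live),
    kind = vapply(frag_sources, function(src) {
      if (length(src) == 2L) "merged_disulfide"
      else switch(res$kind[src], amino_acid = "residue", res$kind[src])
    }, character(1)),
    chain  = vapply(frag_sources, function(src) res$chain[src[1]], character(1)),
    resseq = vapply(frag_sources, function(src) res$resseq[src[1]], numeric(1)),
    reskeys = vapply(frag_sources, function(src)
      paste(res$reskey[src], collapse = "+"), character(1)),
    stringsAsFactors = FALSE)
  frag$n_atoms <- as.integer(table(factor(frag_of_atom, levels = frag$index)))
  if (any(frag$n_atoms == 0L)) stopf("internal error: empty fragment")
  frag$label <- vapply(frag_sources, function(src)
    paste(fragment_label(res$resname[src], res$resseq[src], res$chain[src],
                         kind = ifelse(res$kind[src] == "water", "water",
                                       res$kind[src]),
                         notation = notation), collapse = "-"), character(1))

  plan <- list(fragments = frag,
               assignment = data.frame(serial = atoms$serial,
                                       fragment = frag_of_atom),
               detached = detached,
               sources = frag_sources,
               merged_pairs = merged_pairs,
               n_fragments = nrow(frag),
               total_charge = NA_integer_)
  class(plan) <- "spies_plan"
  assign_formal_charges(plan, structure, ligand_charges = ligand_charges)
}

#' @export
print.spies_plan <- function(x, ...) {
  cat(sprintf(
    "<spies_plan> %d fragments (%d residue, %d water, %d ligand, %d merged disulfide), %d detached bonds, total charge %+d\n",
    x$n_fragments,
    sum(x$fragments$kind == "residue"), sum(x$fragments$kind == "water"),
    sum(x$fragments$kind == "ligand"),
    sum(x$fragments$kind == "merged_disulfide"),
    nrow(x$detached), x$total_charge))
  invisible(x)
}

residue_formal_charge <- function(structure, reskey, is_nterm, is_cterm,
                                  ligand_charges = NULL) {
  res <- structure$residues
  i <- match(reskey, res$reskey)
  kind <- res$kind[i]
  if (kind == "water") return(0L)
  if (kind %in% c("ligand", "other")) {
    lc <- 0
    if (!is.null(ligand_charges)) {
      nm <- names(ligand_charges)
      if (reskey %in% nm) lc <- ligand_charges[[reskey]]
      else if (res$resname[i] %in% nm) lc <- ligand_charges[[res$resname[i]]]
    }
    return(as.integer(lc))
  }
  at <- structure$atoms[structure$atoms$reskey == reskey, ]
  rn <- canonical_resname(res$resname[i])
  raw <- toupper(res$resname[i])
  has <- function(nms) any(at$name %in% nms)
  if (!any(at$is_hydrogen)) {
    warnf("residue %s has no hydrogens; falling back to name-based charge rule",
          reskey)
    side <- switch(rn, ASP = -1L, GLU = -1L, LYS = 1L, ARG = 1L,
                   HIS = if (raw == "HIP") 1L else 0L, 0L)
    term <- (if (is_cterm && has("OXT")) -1L else 0L) +
      (if (is_nterm) 1L else 0L)
    return(side + term)
  }
  side <- switch(rn,
    ASP = if (has(c("HD1", "HD2"))) 0L else -1L,
    GLU = if (has(c("HE1", "HE2"))) 0L else -1L,
    LYS = if (sum(at$name %in% c("HZ1", "HZ2", "HZ3")) >= 3L) 1L else 0L,
    ARG = 1L,
    HIS = if (has("HD1") && has("HE2")) 1L else 0L,
    0L)
  nterm <- 0L
  if (is_nterm &&
      sum(at$name %in% c("H1", "H2", "H3", "HT1", "HT2", "HT3")) >= 3L)
    nterm <- 1L
  cterm <- 0L
  if (is_cterm && has("OXT") && !has(c("HXT", "HO")))
    cterm <- -1L
  side + nterm + cterm
}

#' Assign formal charges to a fragmentation plan
#'
#' Charges are inferred from the hydrogen atoms present (the protonation
#' state fixed upstream), not from residue names alone: carboxylates
#' without an acid hydrogen are -1, Lys with three NZ hydrogens and Arg are
#' +1, His is +1 only when both ring nitrogens are protonated, a free
#' N-terminus with three N hydrogens is +1, and a C-terminus with a bare
#' OXT is -1.  Residues without any hydrogens fall back to a name-based
#' rule with a warning.  Water is 0; ligand charges come from
#' `ligand_charges`.
#'
#' @param plan a `spies_plan`.
#' @param structure the structure the plan was built from.
#' @param ligand_charges named numeric vector (by residue name or key).
#' @return the plan with per-fragment `charge` and `total_charge` filled.
#' @export
assign_formal_charges <- function(plan, structure, ligand_charges = NULL) {
  res <- structure$residues
  # terminal flags per residue (first/last amino acid of its chain)
  is_nterm <- is_cterm <- rep(FALSE, nrow(res))
  for (ch in unique(res$chain)) {
    aa <- which(res$chain == ch & res$kind == "amino_acid")
    if (length(aa)) { is_nterm[aa[1]] <- TRUE; is_cterm[aa[length(aa)]] <- TRUE }
  }
  res_charge <- vapply(seq_len(nrow(res)), function(i)
    residue_formal_charge(structure, res$reskey[i], is_nterm[i], is_cterm[i],
                          ligand_charges), integer(1))
  plan$fragments$charge <- vapply(plan$sources, function(src)
    sum(res_charge[src]), integer(1))
  plan$total_charge <- sum(plan$fragments$charge)
  plan
}

#' Format fragment labels
#'
#' Residues become one-letter code + author residue number with a
#' configured chain affix; waters become `"HOH" + resseq`; unknown residue
#' names fall back to the three-letter code.  With `notation = NULL` the
#' label is `<code><resseq>:<chain>`.  `notation` is a list with optional
#' `prefix` and `suffix` named character vectors mapping chain ids to affix
#' strings: a prefix is prepended (`prefix = c(B = "L")` gives `"LY56"`),
#' a suffix is appended after a caret (`suffix = c(A = "A")` gives
#' `"HOH202^A"`).
#'
#' @param resname,resseq,chain vectors describing the residues.
#' @param kind residue kind (`"water"` labels use the HOH form).
#' @param notation `NULL` or `list(prefix = , suffix = )`.
#' @return character vector of labels.
#' @export
fragment_label <- function(resname, resseq, chain, kind = "residue",
                           notation = NULL) {
  n <- max(length(resname), length(resseq), length(chain))
  resname <- rep_len(resname, n); resseq <- rep_len(resseq, n)
  chain <- rep_len(chain, n); kind <- rep_len(kind, n)
  one <- AA_ONE[canonical_resname(resname)]
  core <- ifelse(kind == "water", paste0("HOH", resseq),
                 ifelse(is.na(one), paste0(toupper(resname), resseq),
                        paste0(one, resseq)))
  if (is.null(notation)) return(paste0(core, ":", chain))
  affix <- function(map, ch) {
    if (!is.null(map) && ch %in% names(map)) map[[ch]] else ""
  }
  pre <- vapply(chain, function(ch) affix(notation$prefix, ch), character(1))
  suf <- vapply(chain, function(ch) {
    s <- affix(notation$suffix, ch)
    if (nzchar(s)) paste0("^", s) else ""
  }, character(1))
  paste0(pre, core, suf)
}

#' Relabel a plan's fragments with a notation map
#'
#' @param plan a `spies_plan`.
#' @param structure the structure the plan was built from.
#' @param notation see [fragment_label()].
#' @return the plan with `fragments$label` rewritten.
#' @export
relabel_fragments <- function(plan, structure, notation = NULL) {
  res <- structure$residues
  plan$fragments$label <- vapply(plan$sources, function(src)
    paste(fragment_label(res$resname[src], res$resseq[src], res$chain[src],
                         kind = ifelse(res$kind[src] == "water", "water",
                                       res$kind[src]),
                         notation = notation), collapse = "-"), character(1))
  if (anyDuplicated(plan$fragments$label))
    warnf("fragment labels are not unique under this notation")
  plan
}

#' Serialize a fragmentation plan to JSON
#' @param plan a `spies_plan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  payload <- list(
    n_fragments = plan$n_fragments,
    total_charge = plan$total_charge,
    fragments = plan$fragments,
    assignment = plan$assignment,
    detached = plan$detached,
    sources = plan$sources,
    merged_pairs = plan$merged_pairs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a fragmentation plan from JSON
#' @param path path written by [write_plan_json()].
#' @return a `spies_plan`.
#' @export
read_plan_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- list(
    fragments = as.data.frame(p$fragments, stringsAsFactors = FALSE),
    assignment = as.data.frame(p$assignment),
    detached = if (length(p$detached)) as.data.frame(p$detached)
               else data.frame(bda_serial = integer(), baa_serial = integer(),
                               owner_fragment = integer()),
    sources = lapply(p$sources, as.integer),
    merged_pairs = as.data.frame(p$merged_pairs, stringsAsFactors = FALSE),
    n_fragments = p$n_fragments,
    total_charge = p$total_charge)
  class(plan) <- "spies_plan"
  plan
}
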