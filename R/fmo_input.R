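# GAMESS-dialect FMO input deck generation.
#
# Atom references inside the deck (INDAT assignment lists and FMOBND
# detached-bond pairs) use sequential FMOXYZ order, the numbering GAMESS
# itself applies; the emitted deck is byte-deterministic for a fixed plan.

ELEMENT_Z <- c(H = 1, C = 6, N = 7, O = 8, F = 9, NA_ = 11, MG = 12, P = 15,
               S = 16, CL = 17, K = 19, CA_ = 20, FE = 26, ZN = 30, BR = 35,
               I = 53)

element_z <- function(el) {
  z <- ELEMENT_Z[toupper(el)]
  z[is.na(z)] <- 0
  unname(z)
}

# canned ideal-sp3 hybrid orbital block (1 core + 4 tetrahedral hybrids on
# the bond-detached carbon); coefficients are geometric sp3 constants, not
# SCF-derived, and can be overridden via params$fmohyb
canned_fmohyb <- function(basis) {
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  rows <- c(sprintf("  1 0  %s", paste(sprintf("%9.6f", c(1, rep(0, 4))),
                                       collapse = " ")))
  for (k in 1:4) {
    co <- c(0, 0.5, 0.5 * dirs[k, ])
    rows <- c(rows, sprintf("  0 1  %s", paste(sprintf("%9.6f", co),
                                               collapse = " ")))
  }
  paste(c(sprintf(" %s 5 5", basis), rows), collapse = "\n")
}

#' FMO job settings
#'
#' @param theory correlation treatment keyword (default `"MP2"`).
#' @param basis basis-set label (default `"6-31G**"`).
#' @param pcm include a polarizable continuum solvent block.
#' @param nbody FMO expansion order (default 2).
#' @param mwords GAMESS memory request.
#' @param fmohyb optional replacement text for the hybrid-orbital block.
#' @return list of settings for [write_fmo_input()].
#' @export
fmo_params <- function(theory = "MP2", basis = "6-31G**", pcm = TRUE,
                       nbody = 2, mwords = 512, fmohyb = NULL) {
  list(theory = theory, basis = basis, pcm = pcm, nbody = nbody,
       mwords = mwords, fmohyb = fmohyb)
}

basis_group <- function(basis) {
  switch(basis,
         "6-31G**" = " $BASIS GBASIS=N31 NGAUSS=6 NDFUNC=1 NPFUNC=1 $END",
         "6-31G*"  = " $BASIS GBASIS=N31 NGAUSS=6 NDFUNC=1 $END",
         "STO-3G"  = " $BASIS GBASIS=STO NGAUSS=3 $END",
         sprintf(" $BASIS GBASIS=%s $END", basis))
}

#' Write a GAMESS-style FMO input deck
#'
#' Emits fragment count, per-fragment charges, the atom-to-fragment
#' assignment (contiguous run-length lists), detached Calpha-C bond pairs,
#' Cartesian coordinates, and job keywords.  Deterministic: the same plan
#' serializes to byte-identical text.
#'
#' @param plan a `spies_plan`.
#' @param structure the matching `spies_structure`.
#' @param params settings from [fmo_params()].
#' @param path optional output path.
#' @return the deck as a single character string (invisibly when `path`
#'   is given).
#' @export
write_fmo_input <- function(plan, structure, params = fmo_params(),
                            path = NULL) {
  atoms <- structure$atoms
  if (anyDuplicated(atoms$serial)) stopf("atom serial collisions in structure")
  if (any(plan$fragments$n_atoms == 0L)) stopf("fragment with zero atoms")
  if (nrow(atoms) != nrow(plan$assignment) ||
      !all(atoms$serial == plan$assignment$serial))
    stopf("plan does not match structure atom list")

  pos_of_serial <- stats::setNames(seq_len(nrow(atoms)), atoms$serial)
  frag_of_pos <- plan$assignment$fragment

  charges <- plan$fragments$charge
  icharg_lines <- strwrap(paste(sprintf("%d", charges), collapse = ", "),
                          width = 60)
  icharg <- paste0("   ICHARG(1)= ", paste(icharg_lines, collapse = "\n              "))

  indat_lines <- vapply(seq_len(plan$n_fragments), function(f) {
    r <- int_runs(which(frag_of_pos == f))
    toks <- ifelse(r$start == r$end, sprintf("%d", r$start),
                   sprintf("%d -%d", r$start, r$end))
    sprintf("      %s 0", paste(toks, collapse = " "))
  }, character(1))

  ctrl <- sprintf(" $CONTRL SCFTYP=RHF%s RUNTYP=ENERGY ISPHER=1 $END",
                  if (identical(params$theory, "MP2")) " MPLEVL=2" else "")
  sections <- c(
    sprintf("! FMO%d/%s/%s%s deck generated by spies3d",
            params$nbody, params$theory, params$basis,
            if (isTRUE(params$pcm)) "/PCM" else ""),
    ctrl,
    sprintf(" $SYSTEM MWORDS=%d $END", params$mwords),
    basis_group(params$basis),
    if (isTRUE(params$pcm)) " $PCM SOLVNT=WATER IEF=-10 ICOMP=2 $END",
    " $FMO",
    sprintf("   NFRAG=%d NBODY=%d", plan$n_fragments, params$nbody),
    icharg,
    "   INDAT(1)= 0",
    indat_lines,
    " $END",
    " $FMOHYB",
    params$fmohyb %||% canned_fmohyb(params$basis),
    " $END")

  if (nrow(plan$detached)) {
    bnd <- sprintf("  -%d %d %s",
                   pos_of_serial[as.character(plan$detached$bda_serial)],
                   pos_of_serial[as.character(plan$detached$baa_serial)],
                   params$basis)
    sections <- c(sections, " $FMOBND", bnd, " $END")
  }

  xyz <- sprintf(" %-4s %4.1f %14.6f %14.6f %14.6f",
                 atoms$name, element_z(atoms$element),
                 atoms$x, atoms$y, atoms$z)
  sections <- c(sections, " $FMOXYZ", xyz, " $END")

  elements <- unique(atoms$element)
  data_lines <- sprintf(" %s %d", elements, element_z(elements))
  sections <- c(sections, " $DATA",
                if (nzchar(structure$title)) structure$title else "FMO deck",
                "C1", data_lines, " $END", "")

  deck <- paste(sections, collapse = "\n")
  if (!is.null(path)) {
    writeLines(deck, path)
    return(invisible(deck))
  }
  deck
}
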