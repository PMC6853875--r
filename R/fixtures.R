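# Synthetic fixtures: toy multi-chain peptides with waters and disulfides,
# and synthetic PIEDA output with planted ground truth.
#
# Toy geometry is an idealized extended conformation (standard bond
# lengths, no secondary structure): only distances, never energies, derive
# from geometry, so this is sufficient for exercising the full pipeline.

#' Specification for a toy complex
#'
#' @param n_chains number of peptide chains (ids A, B, C, ...).
#' @param residues_per_chain residues in each chain.
#' @param sequence `"polyA"` or a one-letter sequence string applied to
#'   every chain (side chains beyond C-beta are idealized methyl stubs,
#'   except CYS which carries an SG).
#' @param inter_chain_gap nearest-atom gap between consecutive chains,
#'   Angstrom.
#' @param n_waters number of water molecules.
#' @param water_placement `"interface"` (midway between the nearest
#'   inter-chain Calpha pairs) or `"random"` (uniform in the bounding box).
#' @param disulfides list of `list(chain_a=, resseq_a=, chain_b=,
#'   resseq_b=)`; the named residues become SG-bonded cysteines 2.05 A
#'   apart.
#' @param seed integer fixing all randomness.
#' @return validated spec list.
#' @export
toy_complex_spec <- function(n_chains = 2, residues_per_chain = 6,
                             sequence = "polyA", inter_chain_gap = 4.5,
                             n_waters = 0,
                             water_placement = c("interface", "random"),
                             disulfides = list(), seed = 1) {
  stopifnot(n_chains >= 1, residues_per_chain >= 1, inter_chain_gap > 0,
            n_waters >= 0)
  water_placement <- match.arg(water_placement)
  list(n_chains = n_chains, residues_per_chain = residues_per_chain,
       sequence = sequence, inter_chain_gap = inter_chain_gap,
       n_waters = n_waters, water_placement = water_placement,
       disulfides = disulfides, seed = as.integer(seed))
}

CA_SPACING <- 4.28  # per-residue advance giving C-N = 1.33 A

toy_residue_atoms <- function(resname, resseq, nterm, cterm) {
  t <- (resseq - 1) * CA_SPACING
  a <- list()
  put <- function(name, x, y, z) {
    a[[length(a) + 1L]] <<- data.frame(name = name, x = x, y = y, z = z,
                                       stringsAsFactors = FALSE)
  }
  put("N", t, 0, 0)
  if (nterm) {
    put("H1", t - 0.35, -0.90, 0)
    put("H2", t - 0.35, 0.45, 0.80)
    put("H3", t - 0.35, 0.45, -0.80)
  } else {
    put("H", t - 0.35, -0.90, 0)
  }
  put("CA", t + 1.45, 0, 0)
  put("HA", t + 1.45, -0.62, -0.85)
  put("CB", t + 1.45, 1.20, 0.95)
  if (identical(resname, "CYS")) {
    put("HB2", t + 1.45 + 0.90, 1.60, 1.15)
    put("HB3", t + 1.45 - 0.90, 1.60, 1.15)
    put("SG", t + 1.45, 2.70, 1.95)   # overridden when disulfide-bonded
    put("HG", t + 1.45, 3.65, 2.90)
  } else {
    put("HB1", t + 1.45 - 0.90, 1.60, 1.15)
    put("HB2", t + 1.45 + 0.90, 1.60, 1.15)
    put("HB3", t + 1.45, 1.65, -0.00 + 0.05)
  }
  put("C", t + 2.95, 0, 0)
  put("O", t + 2.95, -1.23, 0)
  if (cterm) put("OXT", t + 3.60, 1.05, 0)
  out <- do.call(rbind, a)
  out$resname <- resname
  out$resseq <- resseq
  out
}

toy_chain <- function(sequence, n_res, chain_id) {
  resnames <- if (identical(sequence, "polyA")) {
    rep("ALA", n_res)
  } else {
    letters1 <- strsplit(sequence, "")[[1]]
    if (length(letters1) != n_res)
      stopf("sequence length %d != residues_per_chain %d",
            length(letters1), n_res)
    three <- AA_THREE[toupper(letters1)]
    if (any(is.na(three)))
      stopf("unknown one-letter code(s) in sequence '%s'", sequence)
    unname(three)
  }
  rows <- lapply(seq_len(n_res), function(i)
    toy_residue_atoms(resnames[i], i, nterm = i == 1L, cterm = i == n_res))
  out <- do.call(rbind, rows)
  out$chain <- chain_id
  out
}

# translate chain B along +y so the nearest inter-chain atom gap equals gap
solve_chain_offset <- function(xyz_a, xyz_b, gap) {
  f <- function(dy) {
    b <- xyz_b; b[, 2] <- b[, 2] + dy
    cross_min_dist(xyz_a, b) - gap
  }
  span <- diff(range(c(xyz_a[, 2], xyz_b[, 2])))
  stats::uniroot(f, lower = 0.05, upper = gap + 2 * span + 10,
                 extendInt = "upX", tol = 1e-8)$root
}

#' Generate a toy multi-chain complex
#'
#' Extended-conformation peptide chains with idealized internal geometry,
#' consecutive chains offset so their nearest-atom gap equals
#' `inter_chain_gap`, fully protonated, with optional interface or random
#' waters and disulfide bridges.  Fully reproducible from `spec$seed`.
#'
#' @param spec a [toy_complex_spec()].
#' @return a `spies_structure`.
#' @export
make_toy_complex <- function(spec) {
  spec <- do.call(toy_complex_spec, spec[names(spec) != ""])
  chain_ids <- LETTERS[seq_len(spec$n_chains)]
  chains <- lapply(chain_ids, function(ch)
    toy_chain(spec$sequence, spec$residues_per_chain, ch))
  # stack chains along +y at the requested gap
  if (spec$n_chains > 1L) {
    for (k in 2:spec$n_chains) {
      xyz_prev <- as.matrix(chains[[k - 1L]][, c("x", "y", "z")])
      xyz_k <- as.matrix(chains[[k]][, c("x", "y", "z")])
      dy <- solve_chain_offset(xyz_prev, xyz_k, spec$inter_chain_gap)
      chains[[k]]$y <- chains[[k]]$y + dy
    }
  }
  atoms <- do.call(rbind, chains)
  atoms$het <- FALSE

  # disulfides: retype residues as CYS and place SG atoms 2.05 A apart
  for (ds in spec$disulfides) {
    mask <- function(ch, rs) atoms$chain == ch & atoms$resseq == rs
    if (!any(mask(ds$chain_a, ds$resseq_a)) ||
        !any(mask(ds$chain_b, ds$resseq_b)))
      stopf("impossible disulfide spec: residue %s:%s or %s:%s absent",
            ds$chain_a, ds$resseq_a, ds$chain_b, ds$resseq_b)
    for (side in list(c(ds$chain_a, ds$resseq_a),
                      c(ds$chain_b, ds$resseq_b))) {
      m <- mask(side[1], as.numeric(side[2]))
      atoms$resname[m] <- "CYS"
      drop <- m & atoms$name %in% c("HB1", "HG")
      if (any(drop)) atoms <- atoms[!drop, , drop = FALSE]
    }
    ra <- mask(ds$chain_a, ds$resseq_a)
    rb <- mask(ds$chain_b, ds$resseq_b)
    cb_a <- unlist(atoms[ra & atoms$name == "CB", c("x", "y", "z")])
    cb_b <- unlist(atoms[rb & atoms$name == "CB", c("x", "y", "z")])
    mid <- (cb_a + cb_b) / 2
    u <- (cb_b - cb_a) / sqrt(sum((cb_b - cb_a)^2))
    sg_a <- mid - 1.025 * u
    sg_b <- mid + 1.025 * u
    place_sg <- function(ch, rs, pos) {
      m <- atoms$chain == ch & atoms$resseq == rs
      has <- m & atoms$name == "SG"
      if (any(has)) {
        atoms[has, c("x", "y", "z")] <<- as.list(pos)
      } else {
        tmpl <- atoms[which(m)[1], , drop = FALSE]
        tmpl$name <- "SG"; tmpl$x <- pos[1]; tmpl$y <- pos[2]; tmpl$z <- pos[3]
        atoms <<- rbind(atoms, tmpl)
      }
    }
    place_sg(ds$chain_a, ds$resseq_a, sg_a)
    place_sg(ds$chain_b, ds$resseq_b, sg_b)
  }
  # keep residues contiguous after any appends
  atoms <- atoms[order(match(atoms$chain, chain_ids), atoms$resseq), ,
                 drop = FALSE]

  # waters
  if (spec$n_waters > 0L) {
    wat <- with_preserved_seed(spec$seed, {
      if (spec$water_placement == "interface" && spec$n_chains > 1L) {
        ca1 <- atoms[atoms$chain == chain_ids[1] & atoms$name == "CA",
                     c("x", "y", "z")]
        ca2 <- atoms[atoms$chain == chain_ids[2] & atoms$name == "CA",
                     c("x", "y", "z")]
        d <- cross_dist(as.matrix(ca1), as.matrix(ca2))
        ord <- order(d)
        pick <- ord[seq_len(min(spec$n_waters, length(d)))]
        ij <- arrayInd(pick, dim(d))
        (as.matrix(ca1)[ij[, 1], , drop = FALSE] +
           as.matrix(ca2)[ij[, 2], , drop = FALSE]) / 2
      } else {
        bb <- apply(atoms[, c("x", "y", "z")], 2, range)
        cbind(stats::runif(spec$n_waters, bb[1, 1], bb[2, 1]),
              stats::runif(spec$n_waters, bb[1, 2], bb[2, 2]),
              stats::runif(spec$n_waters, bb[1, 3], bb[2, 3]))
      }
    })
    wrows <- lapply(seq_len(nrow(wat)), function(k) {
      o <- unname(wat[k, ])
      data.frame(name = c("O", "H1", "H2"),
                 x = o[1] + c(0, 0.76, -0.76),
                 y = o[2] + c(0, 0.59, 0.59),
                 z = o[3],
                 resname = "HOH", resseq = 200 + k, chain = "S", het = TRUE,
                 stringsAsFactors = FALSE)
    })
    atoms <- rbind(atoms, do.call(rbind, wrows))
  }

  atoms$serial <- seq_len(nrow(atoms))
  atoms$element <- NA_character_
  atoms$altloc <- ""
  atoms$icode <- ""
  atoms$occupancy <- 1
  new_structure(atoms, title = sprintf(
    "toy complex: %d chain(s) x %d residues, gap %.1f A, %d water(s), seed %d",
    spec$n_chains, spec$residues_per_chain, spec$inter_chain_gap,
    spec$n_waters, spec$seed))
}

#' Specification for synthetic PIEDA output
#'
#' @param planted data.frame of planted pairs with columns `i`, `j`,
#'   `e_es`, `e_ex`, `e_ct_mix`, `e_di`, `g_sol` (see [planted_pair()]);
#'   planted totals must be attractively significant (at or below -3.0
#'   kcal/mol).
#' @param background_range range for the uniform background totals of all
#'   remaining pairs; the default (-2.9, 3.0) never crosses the attractive
#'   threshold.
#' @param g_sol emit a solvation column.
#' @param seed integer fixing the background noise.
#' @return spec list.
#' @export
synthetic_pie_spec <- function(planted = NULL, background_range = c(-2.9, 3.0),
                               g_sol = TRUE, seed = 1) {
  if (is.null(planted))
    planted <- data.frame(i = integer(), j = integer(), e_es = numeric(),
                          e_ex = numeric(), e_ct_mix = numeric(),
                          e_di = numeric(), g_sol = numeric())
  list(planted = planted, background_range = background_range,
       g_sol = g_sol, seed = as.integer(seed))
}

#' Helper: one planted pair row with a prescribed total
#'
#' Splits `total` deterministically into decomposition terms whose sum is
#' exactly `total`.
#'
#' @param i,j fragment indices.
#' @param total desired pair interaction energy, kcal/mol.
#' @param g_sol solvation share of the total.
#' @return one-row data.frame for [synthetic_pie_spec()].
#' @export
planted_pair <- function(i, j, total, g_sol = 0) {
  rem <- total - g_sol
  e_es <- round(0.5 * rem, 3)
  e_di <- round(0.3 * rem, 3)
  e_ex <- round(abs(0.1 * rem), 3)
  e_ct_mix <- rem - e_es - e_di - e_ex
  data.frame(i = i, j = j, e_es = e_es, e_ex = e_ex,
             e_ct_mix = e_ct_mix, e_di = e_di, g_sol = g_sol)
}

#' Generate synthetic PIEDA output text with known ground truth
#'
#' Emits a GAMESS-dialect output (banner, job echo, PIEDA summary block)
#' embedding the planted pairs plus uniform background noise for every
#' remaining fragment pair, and returns the ground-truth table alongside.
#' All values are rounded to the printed precision before the table is
#' built, so parsing the text recovers the table exactly.
#'
#' @param plan a `spies_plan` (defines the fragment count).
#' @param spec a [synthetic_pie_spec()].
#' @return list with elements `text` (character scalar) and `table`
#'   (a [pie_table()]).
#' @export
make_synthetic_fmo_output <- function(plan, spec = synthetic_pie_spec()) {
  n <- plan$n_fragments
  pl <- spec$planted
  if (nrow(pl)) {
    if (any(pl$i >= pl$j)) stopf("planted pairs must have i < j")
    if (any(pl$j > n)) stopf("planted pair out of range (n_fragments = %d)", n)
    tot <- pl$e_es + pl$e_ex + pl$e_ct_mix + pl$e_di + pl$g_sol
    if (any(tot > -3.0))
      stopf("planted pair total(s) above -3.0 kcal/mol are not attractively significant")
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  key <- paste(pairs[, 1], pairs[, 2])
  planted_key <- paste(pl$i, pl$j)
  bg <- pairs[!key %in% planted_key, , drop = FALSE]
  bg_rows <- with_preserved_seed(spec$seed, {
    tot <- stats::runif(nrow(bg), spec$background_range[1],
                        spec$background_range[2])
    raw <- matrix(stats::rnorm(nrow(bg) * 5), ncol = 5)
    if (!spec$g_sol) raw[, 5] <- 0
    shift <- (tot - rowSums(raw)) / if (spec$g_sol) 5 else 4
    comp <- raw + shift
    if (!spec$g_sol) comp[, 5] <- 0
    data.frame(i = bg[, 1], j = bg[, 2], e_es = comp[, 1], e_ex = comp[, 2],
               e_ct_mix = comp[, 3], e_di = comp[, 4], g_sol = comp[, 5])
  })
  all_rows <- rbind(pl, bg_rows)
  all_rows <- all_rows[order(all_rows$i, all_rows$j), , drop = FALSE]
  # round to printed precision, then totals are exact sums of printed terms
  for (cc in c("e_es", "e_ex", "e_ct_mix", "e_di", "g_sol"))
    all_rows[[cc]] <- round(all_rows[[cc]], 3)
  all_rows$total <- round(all_rows$e_es + all_rows$e_ex + all_rows$e_ct_mix +
                            all_rows$e_di + all_rows$g_sol, 3)

  fmt <- function(v) sprintf("%10.3f", v)
  header <- paste0("    I    J DL  Z      R     Q(I->J)",
                   "     TOTAL        ES        EX    CT+MIX        DI",
                   if (spec$g_sol) "       SOL" else "")
  body <- vapply(seq_len(nrow(all_rows)), function(r) {
    paste0(sprintf("%5d%5d%3d%3d%7.2f%12.3f", all_rows$i[r], all_rows$j[r],
                   0L, 0L, 0, 0),
           fmt(all_rows$total[r]), fmt(all_rows$e_es[r]),
           fmt(all_rows$e_ex[r]), fmt(all_rows$e_ct_mix[r]),
           fmt(all_rows$e_di[r]),
           if (spec$g_sol) fmt(all_rows$g_sol[r]) else "")
  }, character(1))
  text <- paste(c(
    " *** GAMESS-style synthetic FMO output (spies3d fixture) ***",
    " EXECUTION OF FMO MODULE",
    sprintf(" NFRAG= %d NBODY= 2", n),
    " ..... DONE WITH MONOMER SCF .....",
    "",
    " -------------------------------------------------------------",
    "       PAIR INTERACTION ENERGY DECOMPOSITION ANALYSIS (PIEDA)",
    "       UNITS ARE KCAL/MOL",
    " -------------------------------------------------------------",
    header, body, "",
    " ..... DONE WITH PIEDA ....."), collapse = "\n")

  tab_rec <- all_rows[, c("i", "j", "e_es", "e_ex", "e_ct_mix", "e_di",
                          "g_sol", "total")]
  names(tab_rec)[1:2] <- c("frag_i", "frag_j")
  if (!spec$g_sol) tab_rec$g_sol <- NA_real_
  list(text = text,
       table = pie_table(tab_rec, n,
                         metadata = list(source = "synthetic",
                                         seed = spec$seed)))
}
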