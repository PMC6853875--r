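# Pipeline orchestration: prep -> fmo-input -> parse -> analyze, with a
# YAML/list configuration, artifact manifest, and determinism guarantees.
#
# The pipeline never invokes the quantum chemistry code: the user runs the
# emitted deck externally and hands the output file back for the parse
# stage (or uses the synthetic fixture mode for desk-scale work).

PIPELINE_STAGES <- c("prep", "fmo_input", "parse", "analyze")

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return config list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' Validate a pipeline configuration
#'
#' Schema checks run before any stage executes: known stage names, an
#' output directory, exactly one structure source (`pdb` or `fixture`),
#' and, once the structure is known, that every chain in the group map
#' exists.
#'
#' @param config config list (see [run_pipeline()]).
#' @param structure optionally, the already-loaded structure for the
#'   chain-map check.
#' @return the config, invisibly; errors on schema violations.
#' @export
validate_run_config <- function(config, structure = NULL) {
  stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (is.null(config$out_dir)) stopf("config lacks out_dir")
  if (is.null(config$pdb) && is.null(config$fixture))
    stopf("config needs a structure source: pdb or fixture")
  if (!is.null(config$pdb) && !is.null(config$fixture))
    stopf("config must give exactly one of pdb / fixture")
  if ("analyze" %in% stages && is.null(config$groups))
    stopf("analyze stage requires a chain group map (groups)")
  if (!is.null(structure) && !is.null(config$groups)) {
    chains <- setdiff(structure$chain_order,
                      structure$residues$chain[structure$residues$kind == "water"])
    unmapped <- setdiff(chains, names(config$groups))
    if (length(unmapped))
      stopf("group map lacks chain(s) present in structure: %s",
            paste(unmapped, collapse = ", "))
    unknown <- setdiff(names(config$groups), structure$chain_order)
    if (length(unknown))
      stopf("group map names unknown chain(s): %s",
            paste(unknown, collapse = ", "))
  }
  invisible(config)
}

#' Run the analysis pipeline from a configuration
#'
#' Config fields: `out_dir`; `pdb` (input structure) or `fixture` (a
#' [toy_complex_spec()] list, optionally with `synthetic: {n_planted:,
#' planted_total:}` to generate matching synthetic PIEDA output); `keep` /
#' `waters_within` (region selection); `groups` (chain to group map);
#' `notation` (label affixes); `params` (distance_cutoff,
#' attractive_threshold, include_repulsive); `gamess_out` (output file to
#' parse); `stages` (subset of prep, fmo_input, parse, analyze); `seed`.
#' Rerunning an identical config reproduces byte-identical artifacts.
#'
#' @param config list or YAML path.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  stages <- config$stages %||% PIPELINE_STAGES
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  artifacts <- character()
  art <- function(name) {
    p <- file.path(out_dir, name)
    artifacts <<- c(artifacts, p)
    p
  }

  # structure source (needed by every stage)
  structure <- if (!is.null(config$pdb)) {
    read_pdb(config$pdb)
  } else {
    make_toy_complex(utils::modifyList(config$fixture,
                                       list(seed = config$fixture$seed %||% seed)))
  }
  validate_run_config(config, structure)

  notation <- config$notation
  params <- do.call(spies_params, config$params %||% list())

  if ("prep" %in% stages) {
    if (!is.null(config$keep))
      structure <- select_region(structure, config$keep,
                                 waters_within = config$waters_within)
    write_pdb(structure, art("prep.pdb"))
  }

  plan <- NULL
  if (any(c("fmo_input", "parse", "analyze") %in% stages)) {
    plan <- build_fragmentation(structure,
                                merge_disulfides = config$merge_disulfides %||% TRUE,
                                ligand_charges = unlist(config$ligand_charges),
                                treat_as_ligand = unlist(config$treat_as_ligand) %||% character(),
                                notation = notation)
    if (!is.null(notation)) plan <- relabel_fragments(plan, structure, notation)
  }
  if ("fmo_input" %in% stages) {
    write_plan_json(plan, art("plan.json"))
    write_fmo_input(plan, structure, params = do.call(
      fmo_params, config$fmo %||% list()), path = art("deck.inp"))
  }

  pie <- NULL
  if ("parse" %in% stages) {
    if (!is.null(config$gamess_out)) {
      if (!file.exists(config$gamess_out))
        stopf("parse stage needs the FMO output file '%s' (not found); run the deck first",
              config$gamess_out)
      pie <- parse_fmo_output(config$gamess_out)
    } else if (!is.null(config$fixture)) {
      syn <- config$synthetic %||% list()
      dist0 <- all_pair_distances(plan, structure,
                                  cutoff = params$distance_cutoff)
      planted <- auto_plant(plan, dist0, n = syn$n_planted %||% 3L,
                            total = syn$planted_total %||% -8,
                            water_bridge = isTRUE(syn$plant_water_bridge))
      gen <- make_synthetic_fmo_output(plan, synthetic_pie_spec(
        planted = planted, seed = syn$seed %||% seed))
      writeLines(gen$text, art("fmo_output.log"))
      pie <- gen$table
    } else {
      stopf("parse stage needs gamess_out (or fixture mode); missing artifact: FMO output")
    }
    write_pie_table(pie, art("pie.csv"), plan = plan)
  }

  if ("analyze" %in% stages) {
    if (is.null(pie)) {
      pie_path <- file.path(out_dir, "pie.csv")
      if (!file.exists(pie_path))
        stopf("analyze stage needs a PIE table; missing artifact: %s (run the parse stage)",
              pie_path)
      pie <- read_pie_table(pie_path)
    }
    distances <- all_pair_distances(plan, structure,
                                    cutoff = params$distance_cutoff,
                                    heavy_atoms_only = params$heavy_atoms_only)
    rec <- spies_filter(pie, distances, plan, params)
    rec <- classify_pairs(rec, unlist(config$groups))
    write_spie_records(rec, art("spie_records.csv"))
    utils::write.csv(detect_water_bridges(rec),
                     art("water_bridges.csv"), row.names = FALSE)
    hs <- do.call(rbind, lapply(unique(unlist(config$groups)), function(g) {
      h <- hotspot_regions(rec, g, gap_tolerance = config$gap_tolerance %||% 2)
      if (nrow(h)) cbind(group = g, h) else NULL
    }))
    if (is.null(hs))
      hs <- data.frame(group = character(), region = integer(),
                       start = numeric(), end = numeric(),
                       n_residues = integer(), residues = character(),
                       support = integer())
    utils::write.csv(hs, art("hotspots.csv"), row.names = FALSE)
    export_scatter(rec, path = art("scatter.json"))
  }

  manifest <- list(
    package = "spies3d",
    version = as.character(utils::packageVersion("spies3d")),
    config = config,
    artifacts = lapply(artifacts, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# pick the n closest inter-chain fragment pairs as planted ground truth;
# optionally also plant both legs of one water bridge (a water fragment
# within the cutoff of fragments in two different chains)
auto_plant <- function(plan, distances, n, total, water_bridge = FALSE) {
  fr <- plan$fragments
  inter <- distances[fr$chain[distances$i] != fr$chain[distances$j] &
                       fr$kind[distances$i] != "water" &
                       fr$kind[distances$j] != "water", , drop = FALSE]
  inter <- inter[order(inter$distance), , drop = FALSE]
  take <- utils::head(inter, n)
  planted <- if (nrow(take) == 0L) synthetic_pie_spec()$planted else
    do.call(rbind, lapply(seq_len(nrow(take)), function(k)
      planted_pair(take$i[k], take$j[k], total)))
  if (water_bridge) {
    waters <- fr$index[fr$kind == "water"]
    for (w in waters) {
      touch <- distances[distances$i == w | distances$j == w, , drop = FALSE]
      partner <- ifelse(touch$i == w, touch$j, touch$i)
      ok <- fr$kind[partner] != "water"
      touch <- touch[ok, , drop = FALSE]; partner <- partner[ok]
      chains <- fr$chain[partner]
      if (length(unique(chains)) < 2L) next
      pick <- c(which(chains == unique(chains)[1])[1],
                which(chains == unique(chains)[2])[1])
      legs <- do.call(rbind, lapply(pick, function(k)
        planted_pair(min(w, partner[k]), max(w, partner[k]), total)))
      planted <- rbind(planted, legs)
      break
    }
  }
  planted
}
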