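#' Validate a pipeline configuration
#'
#' Fail-fast checks run before any computation: referenced paths must
#' exist, every stochastic step must carry a seed, and C-alpha structures
#' require either a cutoff table or a calibration corpus.
#'
#' @param config List (already parsed) or path to a YAML file.
#' @return The validated config list, invisibly annotated with
#'   `config_hash` (md5 of the file when read from disk).
#' @export
validate_config <- function(config) {
  hash <- NULL
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config must set a top-level seed")
  if (is.null(config$output_dir)) stop("config must set output_dir")
  for (st in config$structures) {
    if (!is.null(st$path) && !file.exists(st$path))
      stop("structure path not found: ", st$path)
    if (is.null(st$path) && is.null(st$scenario))
      stop("each structure needs a path or a scenario")
    if (!is.null(st$scenario) && is.null(st$scenario$seed))
      stop("structure scenario without seed")
  }
  needs_calpha <- any(vapply(config$structures, function(st)
    isTRUE(st$calpha), logical(1)))
  if (needs_calpha && is.null(config$cutoff_table) &&
      is.null(config$calibration))
    stop("C-alpha structures present but neither cutoff_table nor ",
         "calibration corpus configured")
  if (!is.null(config$cutoff_table) && !file.exists(config$cutoff_table))
    stop("cutoff table not found: ", config$cutoff_table)
  for (fam in config$conservation$families)
    if (!is.null(fam$path) && !file.exists(fam$path))
      stop("alignment not found: ", fam$path)
  config$config_hash <- hash
  invisible(config)
}

#' Run the end-to-end analysis
#'
#' Orchestrates the full chain from one configuration: structure
#' generation or loading, subcomplex decomposition, SASA and interface
#' detection (all-atom and, with calibrated cutoffs, C-alpha), per-chain
#' conservation comparison of interface against non-interface surface
#' residues, and mirror-tree correlations over the configured family
#' pairs. All intermediates are persisted as TSV/PDB/FASTA/PHYLIP files
#' under `output_dir`; the report is returned and written as JSON.
#' Re-running with the same config and seeds reproduces the report
#' exactly (timestamps excluded).
#'
#' @param config List or path to YAML (see [validate_config()] and the
#'   bundled `inst/extdata/config_synthetic.yaml`).
#' @return `run_report` list with elements `interfaces`, `subcomplexes`,
#'   `conservation`, `mirror`, `provenance`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$output_dir, "run.jsonl")
  log_stage <- function(stage, ...) {
    cat(jsonlite::toJSON(c(list(stage = stage), list(...)), auto_unbox = TRUE),
        "\n", file = logf, append = TRUE)
  }
  n_points <- cfg$n_points %||% 480L
  reference <- cfg$reference %||% "synthetic"
  nb_cutoff <- cfg$neighbor_cutoff %||% 5.0

  # --- structures -----------------------------------------------------
  log_stage("structures", n = length(cfg$structures))
  structs <- list()
  truths <- list()
  for (k in seq_along(cfg$structures)) {
    st <- cfg$structures[[k]]
    if (!is.null(st$path)) {
      s <- read_structure(st$path)
      truth <- NULL
    } else {
      scn <- do.call(complex_scenario, st$scenario)
      gen <- generate_complex(scn)
      s <- if (isTRUE(st$calpha)) gen$calpha else gen$all_atom
      truth <- gen$truth
      write_structure(s, file.path(cfg$output_dir,
                                   sprintf("structure_%d.pdb", k)))
    }
    structs[[k]] <- s
    truths[[k]] <- truth
  }

  # --- cutoff table (for any C-alpha structure) -----------------------
  cutoffs <- NULL
  if (!is.null(cfg$cutoff_table)) {
    cutoffs <- read_cutoff_table(cfg$cutoff_table)
  } else if (!is.null(cfg$calibration)) {
    cal <- cfg$calibration
    train <- lapply(seq_len(cal$n_complexes %||% 6L), function(i)
      generate_complex(complex_scenario(
        length = cal$length %||% 40L,
        seed = (cal$seed %||% 1L) + i))$all_atom)
    cutoffs <- calibrate_calpha_cutoffs(
      train, min_per_type = cal$min_per_type %||% 50L,
      n_points = n_points, reference = reference)
    write_cutoff_table(cutoffs, file.path(cfg$output_dir, "cutoffs.tsv"))
    log_stage("calibrate", n_train = sum(cutoffs$n_train))
  }

  # --- interfaces -----------------------------------------------------
  interfaces <- list()
  subtabs <- list()
  iso_store <- list()
  for (k in seq_along(structs)) {
    s <- structs[[k]]
    regime <- if (all(s$chains$calpha_only)) "calpha" else "all-atom"
    probe <- if (regime == "calpha") 3.5 else 1.4
    subs <- build_subcomplexes(s, nb_cutoff)
    subtabs[[k]] <- data.frame(
      chain = names(subs),
      members = vapply(subs, function(x) paste(x$members, collapse = ""),
                       character(1)), stringsAsFactors = FALSE)
    ifc <- detect_interface_assembly(s, nb_cutoff, regime, cutoffs,
                                     n_points = n_points,
                                     reference = reference)
    iso_store[[k]] <- isolated_profiles(s, probe, n_points, reference)
    interfaces[[k]] <- ifc
    write.table(as.data.frame(ifc),
                file.path(cfg$output_dir, sprintf("interface_%d.tsv", k)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("interface", structure = k, regime = regime,
              n_interface = nrow(ifc))
  }

  # --- conservation (Fig-5-style comparison, per chain) ---------------
  conservation <- list()
  for (fam in cfg$conservation$families) {
    k <- fam$structure %||% 1L
    ch <- fam$chain %||% structs[[k]]$chains$chain_id[1]
    iso <- iso_store[[k]][[ch]]
    part <- classify_surface(iso, interfaces[[k]])
    m <- if (!is.null(fam$path)) {
      read_msa(fam$path, fam$format %||% "fasta", target = fam$target)
    } else {
      scn_args <- fam$scenario
      if (isTRUE(fam$link_to_interface)) {
        # slow sites coincide with the chain's detected interface
        scn_args$n_sites <- nrow(part)
        scn_args$site_classes <-
          ifelse(part$class == "interface", "interface", "surface")
      }
      mm <- simulate_family(do.call(evolution_scenario, scn_args))
      write_msa(mm, file.path(cfg$output_dir,
                              paste0("family_", fam$name, ".fasta")))
      mm
    }
    prof <- conservation_scores(m)
    if (nrow(iso) != nrow(prof))
      stop("family ", fam$name, ": alignment target length (", nrow(prof),
           ") does not match chain ", ch, " length (", nrow(iso), ")")
    cmp <- compare_interface_conservation(prof, part,
                                          n_boot = cfg$n_boot %||% 2000L,
                                          seed = cfg$seed)
    conservation[[fam$name]] <- c(list(chain = ch), cmp)
    log_stage("conservation", family = fam$name,
              difference = cmp$difference)
  }

  # --- mirror-tree correlations ---------------------------------------
  # simulated families marked shared evolve on one common species tree
  # (correlated evolution); unshared families get independent trees and
  # serve as unrelated baselines
  mirror <- NULL
  if (!is.null(cfg$mirror)) {
    mc <- cfg$mirror
    n_taxa <- mc$n_taxa %||% 16L
    set.seed(mc$tree_seed %||% cfg$seed)
    common_tree <- sample_species_tree(n_taxa, mc$tree_depth %||% 1.0)
    mats <- list()
    for (fam in mc$families) {
      m <- if (!is.null(fam$path)) {
        read_msa(fam$path, fam$format %||% "fasta")
      } else {
        tree <- if (isTRUE(fam$shared)) common_tree else {
          set.seed(fam$seed + 500009L)
          tb <- sample_species_tree(n_taxa, mc$tree_depth %||% 1.0)
          tb$tip.label <- common_tree$tip.label
          tb
        }
        simulate_family(evolution_scenario(
          n_taxa = n_taxa, n_sites = mc$n_sites %||% 300L, tree = tree,
          family_scale = fam$scale %||% 1.0, seed = fam$seed))
      }
      dm <- distance_matrix(m, model = mc$model %||% "poisson")
      write_dist_phylip(dm, file.path(cfg$output_dir,
                                      paste0("dist_", fam$name, ".phy")))
      write_tree_newick(nj_tree(dm),
                        file.path(cfg$output_dir,
                                  paste0("tree_", fam$name, ".nwk")))
      mats[[fam$name]] <- dm
    }
    pairs <- do.call(rbind, lapply(mc$pairs, function(p)
      data.frame(a = p$a, b = p$b, role = p$role %||% NA_character_,
                 stringsAsFactors = FALSE)))
    mirror <- mirror_batch(mats, pairs, n_perm = mc$n_perm %||% 999L,
                           seed = cfg$seed)
    write.table(mirror, file.path(cfg$output_dir, "mirror.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("mirror", n_pairs = nrow(mirror))
  }

  report <- list(
    interfaces = lapply(interfaces, as.data.frame),
    subcomplexes = subtabs,
    conservation = conservation,
    mirror = mirror,
    provenance = list(package_version = as.character(utils::packageVersion("coatmap")),
                      seed = cfg$seed, config_hash = cfg$config_hash,
                      n_points = n_points, reference = reference))
  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  class(report) <- "run_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  structures:", length(x$interfaces), "\n")
  cat("  interface residues:",
      paste(vapply(x$interfaces, nrow, integer(1)), collapse = ", "), "\n")
  cat("  conservation comparisons:", length(x$conservation), "\n")
  if (!is.null(x$mirror)) {
    cat("  mirror pairs:\n")
    print(x$mirror[, c("a", "b", "role", "r", "p_value")], row.names = FALSE)
  }
  invisible(x)
}
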