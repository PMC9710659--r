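# End-to-end workflows and the run configuration.
#
# `run_pipeline()` ties the modules into the standard workflows (generate
# synthetic data, featurize, train, predict, evaluate, noise simulation) and
# is what the command-line wrapper in `inst/cli/geosec.R` calls. Every run
# is reproducible from (config, seed): artifacts are plain TSV/PDB text
# files in `out_dir`, and two runs with the same configuration produce
# byte-identical label tables.

#' Pipeline run configuration
#'
#' @param mode Structure mode: `"backbone"` or `"ca"`.
#' @param graph_method `"knn"` (method A, default) or `"threshold"` (method B).
#' @param k Neighbour count for method A (default 2).
#' @param tau Threshold in Angstrom for method B (default 3).
#' @param scheme Label scheme.
#' @param method Classifier: `"mpn"` or `"fos"`.
#' @param k_classifier FOS classifier neighbourhood size.
#' @param eta2 Cosine noise level applied to edge features (0 = none).
#' @param n_proteins,jitter Synthetic dataset size and dihedral noise (deg).
#' @param ablation_augment Training-time ablation fractions (see
#'   [mpn_config()]); `NULL` disables.
#' @param epochs,hidden_dim Training budget and width of the MPN.
#' @param seed Master seed for the run.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("backbone", "ca"), graph_method = c("knn", "threshold"),
                       k = 2, tau = 3, scheme = "alpha-beta-other",
                       method = c("mpn", "fos"), k_classifier = 20,
                       eta2 = 0, n_proteins = 60, jitter = 5,
                       ablation_augment = c(0.1, 0.2),
                       epochs = 120, hidden_dim = 32,
                       seed = 1, out_dir = "geosec-run") {
  mode <- match.arg(mode)
  graph_method <- match.arg(graph_method)
  method <- match.arg(method)
  scheme <- match.arg(scheme, SCHEMES)
  if (!is_number(eta2) || eta2 < 0) stop_config("`eta2` must be >= 0")
  structure(
    list(
      mode = mode, graph_method = graph_method, k = k, tau = tau,
      scheme = scheme, method = method, k_classifier = k_classifier,
      eta2 = eta2, n_proteins = n_proteins, jitter = jitter,
      ablation_augment = ablation_augment,
      epochs = epochs, hidden_dim = hidden_dim,
      seed = as.integer(seed), out_dir = out_dir
    ),
    class = "run_config"
  )
}

config_featurize <- function(config, s) {
  if (structure_mode(s) != config$mode) {
    stop_config(sprintf("structure mode '%s' does not match config mode '%s'",
      structure_mode(s), config$mode))
  }
  g <- featurize_structure(
    s, method = config$graph_method, k = config$k, tau = config$tau
  )
  if (config$eta2 > 0) g <- perturb_graph_cosines(g, config$eta2)
  g
}

#' Save / load a trained model bundle
#'
#' The bundle is a directory holding `config.dcf` (human-readable key-value
#' description of the architecture and training setup) and `params.rds`
#' (the parameter blob plus normalisation statistics).
#'
#' @param model An `mpn_model` or `fos_model`.
#' @param dir Bundle directory (created if needed).
#' @return `dir` (`save_model`) or the model object (`load_model`).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  desc <- if (inherits(model, "mpn_model")) {
    c(
      type = "mpn", scheme = model$config$scheme, mode = model$config$mode,
      hidden_dim = model$config$hidden_dim, n_classes = model$config$n_classes,
      best_epoch = model$best_epoch, best_val_f1 = sprintf("%.6f", model$best_val_f1)
    )
  } else if (inherits(model, "fos_model")) {
    c(
      type = "fos", scheme = model$scheme, k_classifier = model$k,
      n_train = nrow(model$X), n_features = ncol(model$X)
    )
  } else {
    stop_validation("`model` must be an mpn_model or fos_model")
  }
  write.dcf(as.data.frame(t(desc)), file.path(dir, "config.dcf"))
  saveRDS(model, file.path(dir, "params.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  path <- file.path(dir, "params.rds")
  if (!file.exists(path)) {
    abort(sprintf("'%s' is not a model bundle (no params.rds)", dir), class = "geosec_io_error")
  }
  readRDS(path)
}

read_label_tsv <- function(path, scheme) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_ss_labels(tibble::as_tibble(df), scheme = scheme)
}

pipeline_dataset <- function(config) {
  ds <- generate_dataset(
    n_proteins = config$n_proteins, jitter = config$jitter,
    seed = config$seed, scheme = config$scheme
  )
  lapply(ds, function(e) {
    s <- if (config$mode == "ca") {
      as_protein_structure(tibble::as_tibble(e$structure), mode = "ca", source = "synthetic")
    } else {
      e$structure
    }
    list(structure = s, graph = config_featurize(config, s), labels = e$labels)
  })
}

#' Run a pipeline command
#'
#' Commands:
#' * `"synth"`: write `n_proteins` synthetic PDB files plus label TSVs.
#' * `"featurize"`: read `input` (PDB), build the residue graph, write the
#'   edge-list TSV.
#' * `"train"`: generate the synthetic dataset, train the configured
#'   classifier, save the model bundle under `out_dir/model`.
#' * `"predict"`: classify `input` (PDB) with the bundle at `model_dir`,
#'   write and return per-residue labels.
#' * `"evaluate"`: compare `input` (predicted label TSV) against `reference`
#'   (DSSP file or label TSV); write the metrics table.
#' * `"noise-sim"`: Monte-Carlo cosine-noise angle-error table.
#'
#' @param command One of the commands above.
#' @param config A [run_config()].
#' @param input Input path (see command descriptions).
#' @param reference Reference label path for `"evaluate"`.
#' @param model_dir Model bundle directory for `"predict"`.
#' @return Command-specific result (invisibly where a file is the product).
#' @export
run_pipeline <- function(command = c("synth", "featurize", "train", "predict", "evaluate", "noise-sim"),
                         config = run_config(), input = NULL, reference = NULL,
                         model_dir = NULL) {
  command <- match.arg(command)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(command,
    "synth" = {
      ds <- generate_dataset(
        n_proteins = config$n_proteins, jitter = config$jitter,
        seed = config$seed, scheme = config$scheme
      )
      paths <- purrr::imap_chr(ds, function(e, i) {
        stem <- file.path(config$out_dir, sprintf("synthetic_%03d", i))
        write_fixture(e$structure, paste0(stem, ".pdb"))
        write_labels(e$labels, paste0(stem, "_labels.tsv"))
        paste0(stem, ".pdb")
      })
      invisible(tibble::tibble(pdb = paths))
    },
    "featurize" = {
      if (is.null(input)) stop_config("featurize needs `input` (a PDB path)")
      s <- read_structure(input, mode = config$mode)
      g <- config_featurize(config, s)
      out <- file.path(config$out_dir, paste0(basename(input), ".edges.tsv"))
      write_graph(g, out)
      invisible(g)
    },
    "train" = {
      prep <- pipeline_dataset(config)
      model <- if (config$method == "mpn") {
        train_model(prep, mpn_config(
          scheme = config$scheme, mode = config$mode,
          hidden_dim = config$hidden_dim, epochs = config$epochs,
          ablation_augment = config$ablation_augment, seed = config$seed
        ))
      } else {
        feats <- dplyr::bind_rows(lapply(prep, function(e) fos_features(e$graph)))
        y <- unlist(lapply(prep, function(e) e$labels$class_id))
        fos_fit(feats, y, k_classifier = config$k_classifier, scheme = config$scheme)
      }
      save_model(model, file.path(config$out_dir, "model"))
      invisible(model)
    },
    "predict" = {
      if (is.null(input) || is.null(model_dir)) {
        stop_config("predict needs `input` (PDB) and `model_dir`")
      }
      model <- load_model(model_dir)
      s <- read_structure(input, mode = config$mode)
      g <- config_featurize(config, s)
      labels <- if (inherits(model, "mpn_model")) {
        if (model$config$mode != config$mode) {
          stop_config(sprintf("a %s-mode model cannot score a %s-mode graph",
            model$config$mode, config$mode))
        }
        predict(model, g)
      } else {
        pred <- predict(model, fos_features(g))
        new_ss_labels(
          tibble::tibble(
            res_id = g$nodes$res_id, chain = g$nodes$chain,
            resnum = g$nodes$resnum, class_id = pred
          ),
          scheme = model$scheme
        )
      }
      out <- file.path(config$out_dir, paste0(basename(input), ".labels.tsv"))
      write_labels(labels, out)
      invisible(labels)
    },
    "evaluate" = {
      if (is.null(input) || is.null(reference)) {
        stop_config("evaluate needs `input` (predicted TSV) and `reference` (DSSP or label TSV)")
      }
      pred <- read_label_tsv(input, scheme = config$scheme)
      true <- if (grepl("\\.tsv$", reference)) {
        read_label_tsv(reference, scheme = config$scheme)
      } else {
        map_labels(read_dssp(reference), scheme = config$scheme)
      }
      rep <- macro_prf(true, pred, scheme = config$scheme)
      utils::write.table(
        glance(rep), file.path(config$out_dir, "metrics.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      rep
    },
    "noise-sim" = {
      sim <- monte_carlo_omega_error(
        eta2 = if (config$eta2 > 0) config$eta2 else c(0.05, 0.1),
        seed = config$seed
      )
      utils::write.table(
        sim, file.path(config$out_dir, "omega_error.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      sim
    }
  )
}
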