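## Configuration-driven orchestration: clean -> (pretrain) -> finetune ->
## explain -> report, with seeded determinism and per-stage manifests.

#' Compute every requested attribution method from one shared trace
#'
#' The six trace-based methods share a single forward pass and a single
#' backward pass; IG and SHAP run their own passes.  Used by the explain
#' stage to avoid recomputing traces per method.
#'
#' @param model a model handle.
#' @param seq a \linkS4class{TokenSequence}.
#' @param methods character vector of method names.
#' @param classIndex class of interest; default the predicted class.
#' @param ig_steps,shap_budget,seed method parameters.
#' @param rollout_literal as-printed rollout variant.
#' @return named list of raw \linkS4class{Attribution} objects.
#' @export
attributeAllMethods <- function(model, seq, methods = ATTRIBUTION_METHODS,
                                classIndex = NULL, ig_steps = 16L,
                                shap_budget = 2L, seed = 1L,
                                rollout_literal = FALSE) {
  methods <- match.arg(methods, ATTRIBUTION_METHODS, several.ok = TRUE)
  out <- list()
  trace_based <- intersect(methods, c("AttentionMaps", "Rollout", "Grads",
                                      "AttGrads", "CAT", "AttCAT"))
  if (length(trace_based)) {
    ft <- forwardWithTrace(model, seq)
    if (is.null(classIndex)) classIndex <- ft$prediction$class
    gr <- NULL
    if (length(intersect(trace_based, c("Grads", "AttGrads", "CAT", "AttCAT"))))
      gr <- classGradients(model, seq, classIndex)
    for (meth in trace_based) {
      out[[meth]] <- switch(meth,
        AttentionMaps = attentionMapAttribution(ft$trace, classIndex),
        Rollout = rolloutAttribution(ft$trace, literal = rollout_literal,
                                     classIndex = classIndex),
        Grads = gradAttribution(ft$trace, gr),
        AttGrads = attgradAttribution(ft$trace, gr),
        CAT = catAttribution(ft$trace, gr),
        AttCAT = attcatAttribution(ft$trace, gr))
    }
  }
  if ("IG" %in% methods)
    out$IG <- integratedGradients(model, seq, steps = ig_steps,
                                  classIndex = classIndex)
  if ("SHAP" %in% methods)
    out$SHAP <- suppressWarnings(
      shapAttribution(model, seq, budget = shap_budget, seed = seed,
                      classIndex = classIndex))
  out[methods]
}

## aligned attributions for all methods across augmentations of one molecule
.augmented_all_methods <- function(model, smiles, methods, n_augment, seed,
                                   ig_steps, shap_budget, rollout_literal = FALSE) {
  can <- canonicalSmiles(smiles)
  strs <- c(can, enumerateSmiles(can, n_augment, seed = seed))
  pad_to <- max(vapply(strs, function(s) length(.scan_tokens(s)), 0L)) + 2L
  fw <- .classifier_forward(model, tokenizeSmiles(can, pad_to = pad_to)@ids)
  classIndex <- which.max(fw$logits)
  per_method <- stats::setNames(vector("list", length(methods)), methods)
  for (k in seq_along(strs)) {
    sq <- tokenizeSmiles(strs[k], pad_to = pad_to)
    ranks <- canonicalAtomRanks(strs[k])
    # low-step IG trades completeness for runtime here; the gap stays
    # recorded in each attribution's provenance
    atts <- suppressWarnings(
      attributeAllMethods(model, sq, methods, classIndex = classIndex,
                          ig_steps = ig_steps, shap_budget = shap_budget,
                          seed = seed + k, rollout_literal = rollout_literal))
    for (meth in methods) {
      al <- alignAtomAttributions(normalizeAttribution(atts[[meth]]), sq,
                                  ranks = ranks, moleculeId = can)
      per_method[[meth]] <- c(per_method[[meth]], list(al))
    }
  }
  per_method
}

#' Demo experiment configuration
#'
#' The shipped desk-scale demonstration: 500 synthetic molecules with a
#' planted nitro alert, a 2-layer, 64-dimensional encoder, all eight
#' attribution methods on 50 test molecules with ten augmentations each,
#' and a never-trained randomized-model control alongside the trained
#' model.
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param workdir artifact directory (default a fresh temporary directory).
#' @return an experiment-config list (see \code{\link{runStage}}).
#' @export
makeDemoConfig <- function(seed = 1L, workdir = tempfile("xairob_demo_")) {
  seed <- as.integer(seed)
  list(
    name = "synthetic-demo",
    paths = list(workdir = workdir),
    synthetic = list(n = 500L, planted_alert = "[N+](=O)[O-]",
                     alert_smarts = "[N+](=O)[O-]", epsilon = 0.1),
    model = list(maxLen = 70L, embedDim = 64L, nHeads = 4L, nLayers = 2L,
                 ffDim = 128L, dropout = 0, architecture = "encoder_only",
                 headType = "maxpool_mlp"),
    pretrain = list(enabled = FALSE, regimen = "ME2C", epochs = 10L),
    finetune = list(encoder = "random", freeze = TRUE, split = "random",
                    epochs = 40L, lr = 3e-3),
    explain = list(methods = ATTRIBUTION_METHODS, n_molecules = 50L,
                   n_augment = 10L, ig_steps = 16L, shap_budget = 2L,
                   rollout_literal = FALSE, include_random_control = TRUE),
    analysis = list(signed_importance = FALSE, class_select = "predicted"),
    seeds = list(corpus = seed, build = seed + 1L, pretrain = seed + 2L,
                 finetune = seed + 3L, explain = seed + 4L)
  )
}

.stage_file <- function(config, what) file.path(config$paths$workdir, what)

#' Read an experiment configuration from YAML
#'
#' Fields missing from the file are filled from the demo defaults
#' (\code{\link{makeDemoConfig}}), so a minimal YAML overriding a few
#' values is enough.
#'
#' @param path YAML file.
#' @param seed master seed used for defaulted seed fields.
#' @return an experiment-config list.
#' @export
readExperimentConfig <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  base <- makeDemoConfig(seed = seed)
  merge_into <- function(base, user) {
    for (k in names(user)) {
      base[[k]] <- if (is.list(user[[k]]) && is.list(base[[k]]))
        merge_into(base[[k]], user[[k]]) else user[[k]]
    }
    base
  }
  merge_into(base, user)
}

#' Write an experiment configuration to YAML
#' @param config an experiment-config list.
#' @param path output YAML file.
#' @return the path, invisibly.
#' @export
writeExperimentConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run one pipeline stage
#'
#' Stages: \code{clean} (generate/load and clean the corpus),
#' \code{pretrain} (auto-translation pre-training, optional),
#' \code{finetune} (transfer-learn the classifier; also writes the
#' randomized control), \code{explain} (attribute augmented test
#' molecules with every configured method for the trained model and the
#' control), \code{report} (robustness summaries).  Each stage writes its
#' artifact plus a JSON manifest into the config's workdir; a missing
#' upstream artifact is an error naming the stage to run first.
#'
#' @param config an experiment config (see \code{\link{makeDemoConfig}}).
#' @param stage one of "clean", "pretrain", "finetune", "explain",
#'   "report".
#' @return the stage artifact (invisible for side-effect-heavy stages).
#' @export
runStage <- function(config, stage = c("clean", "pretrain", "finetune",
                                       "explain", "report")) {
  stage <- match.arg(stage)
  dir.create(config$paths$workdir, showWarnings = FALSE, recursive = TRUE)
  need <- function(f, from) {
    p <- .stage_file(config, f)
    if (!file.exists(p))
      .stopf("missing artifact '%s': run stage '%s' first", f, from)
    p
  }
  manifest <- function(inputs, outputs) {
    man <- list(stage = stage, config_digest = .object_digest(config),
                inputs = inputs,
                outputs = lapply(outputs, function(f)
                  unname(tools::md5sum(.stage_file(config, f)))),
                seed = config$seeds[[switch(stage, clean = "corpus",
                                            pretrain = "pretrain",
                                            finetune = "finetune",
                                            explain = "explain",
                                            report = "explain")]])
    jsonlite::write_json(man, .stage_file(config, paste0("manifest_", stage, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    man
  }

  if (stage == "clean") {
    corpus <- if (!is.null(config$paths$data)) {
      raw <- readSmilesFile(config$paths$data)
      cleanStructures(raw$smiles, raw$label, raw$id)
    } else {
      generateSyntheticMolecules(config$synthetic$n,
                                 seed = config$seeds$corpus,
                                 planted_alert = config$synthetic$planted_alert,
                                 epsilon = config$synthetic$epsilon)
    }
    out <- .stage_file(config, "dataset.csv")
    utils::write.csv(corpus, out, row.names = FALSE)
    manifest(inputs = list(), outputs = list("dataset.csv"))
    return(invisible(corpus))
  }

  if (stage == "pretrain") {
    ds <- utils::read.csv(need("dataset.csv", "clean"), stringsAsFactors = FALSE)
    cfg <- do.call(modelConfig, config$model)
    mod <- buildModel(cfg, seed = config$seeds$build)
    pt <- pretrain(mod, ds, regimen = config$pretrain$regimen,
                   epochs = config$pretrain$epochs, seed = config$seeds$pretrain)
    saveRDS(pt, .stage_file(config, "pretrained.rds"))
    utils::write.csv(pt$history, .stage_file(config, "pretrain_history.csv"),
                     row.names = FALSE)
    manifest(inputs = list(dataset = unname(tools::md5sum(.stage_file(config, "dataset.csv")))),
             outputs = list("pretrain_history.csv"))
    return(invisible(pt))
  }

  if (stage == "finetune") {
    ds <- utils::read.csv(need("dataset.csv", "clean"), stringsAsFactors = FALSE)
    cfg <- do.call(modelConfig, config$model)
    encoder <- if (identical(config$finetune$encoder, "pretrained")) {
      readRDS(need("pretrained.rds", "pretrain"))$model
    } else {
      randomizeModel(cfg, seed = config$seeds$build)
    }
    tl <- transferLearn(encoder, ds, freeze = config$finetune$freeze,
                        split = config$finetune$split,
                        epochs = config$finetune$epochs,
                        lr = config$finetune$lr, seed = config$seeds$finetune)
    control <- randomizeModel(cfg, seed = config$seeds$build + 100L)
    saveRDS(list(trained = tl, control = control),
            .stage_file(config, "classifier.rds"))
    jsonlite::write_json(tl$metrics, .stage_file(config, "finetune_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest(inputs = list(dataset = unname(tools::md5sum(.stage_file(config, "dataset.csv")))),
             outputs = list("finetune_metrics.json"))
    return(invisible(tl))
  }

  if (stage == "explain") {
    art <- readRDS(need("classifier.rds", "finetune"))
    test <- art$trained$split$test
    nmol <- min(config$explain$n_molecules, nrow(test))
    mols <- test[seq_len(nmol), , drop = FALSE]
    models <- list(trained = art$trained$model)
    if (isTRUE(config$explain$include_random_control))
      models$random <- art$control
    methods <- config$explain$methods
    res <- list()
    for (mn in names(models)) {
      for (i in seq_len(nrow(mols))) {
        per <- .augmented_all_methods(models[[mn]], mols$smiles[i], methods,
                                      n_augment = config$explain$n_augment,
                                      seed = config$seeds$explain + i,
                                      ig_steps = config$explain$ig_steps,
                                      shap_budget = config$explain$shap_budget,
                                      rollout_literal = isTRUE(config$explain$rollout_literal))
        res[[mn]][[mols$smiles[i]]] <- per
      }
    }
    saveRDS(list(aligned = res, molecules = mols),
            .stage_file(config, "attributions.rds"))
    manifest(inputs = list(classifier = "classifier.rds"),
             outputs = list())
    return(invisible(res))
  }

  # report
  art <- readRDS(need("attributions.rds", "explain"))
  rep <- robustnessReport(art$aligned, art$molecules,
                          alert_smarts = config$synthetic$alert_smarts,
                          signed = isTRUE(config$analysis$signed_importance))
  utils::write.csv(rep$sample_distances,
                   .stage_file(config, "in_between_sample.csv"), row.names = FALSE)
  utils::write.csv(rep$method_distances,
                   .stage_file(config, "in_between_method.csv"), row.names = FALSE)
  jsonlite::write_json(rep$summary, .stage_file(config, "report_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest(inputs = list(attributions = "attributions.rds"),
           outputs = list("in_between_sample.csv", "in_between_method.csv",
                          "report_summary.json"))
  invisible(rep)
}

#' Robustness report over explained molecules
#'
#' Aggregates aligned augmented attributions into the three robustness
#' views: per-molecule in-between-sample robustness scores (mean pairwise
#' cosine distance over augmentations), in-between-method distances on
#' canonical versus TTA-averaged vectors, entropy, relative alert
#' importance, and the carbon-count diagnostic.
#'
#' @param aligned nested list: model -> molecule smiles -> method -> list
#'   of \linkS4class{AlignedAtomAttribution} (canonical first), as produced
#'   by the explain stage.
#' @param molecules data.frame of the explained molecules.
#' @param alert_smarts optional SMARTS of the planted/reference alert for
#'   relative-importance analysis.
#' @param signed use signed relative importance.
#' @return list with tidy data.frames (\code{sample_distances},
#'   \code{method_distances}, \code{entropy}, \code{alert_importance}) and
#'   a \code{summary} list.
#' @export
robustnessReport <- function(aligned, molecules, alert_smarts = NULL,
                             signed = FALSE) {
  sample_rows <- list(); method_rows <- list(); entropy_rows <- list()
  alert_rows <- list()
  alerts <- if (!is.null(alert_smarts)) alertSet("alert", alert_smarts) else NULL
  for (mn in names(aligned)) {
    for (mol in names(aligned[[mn]])) {
      per <- aligned[[mn]][[mol]]
      methods <- names(per)
      can_vecs <- list(); avg_vecs <- list()
      for (meth in methods) {
        sets <- per[[meth]]
        pc <- tryCatch(pairwiseCosineMatrix(sets), error = function(e) NULL)
        if (!is.null(pc))
          sample_rows[[length(sample_rows) + 1L]] <- data.frame(
            model = mn, molecule = mol, method = meth, score = pc$score,
            n_undefined = pc$n_undefined, stringsAsFactors = FALSE)
        can_vecs[[meth]] <- sets[[1L]]
        avg_vecs[[meth]] <- ttaAverage(sets)
        entropy_rows[[length(entropy_rows) + 1L]] <- data.frame(
          model = mn, molecule = mol, method = meth,
          entropy = attributionEntropy(sets[[1L]]), stringsAsFactors = FALSE)
      }
      for (variant in c("canonical", "tta_average")) {
        vv <- if (variant == "canonical") can_vecs else avg_vecs
        if (length(vv) >= 2L) {
          cg <- crossGroupDistances(lapply(vv, function(v)
            stats::setNames(list(v), mol)), axis = "method")
          if (nrow(cg$distances)) {
            cg$distances$model <- mn
            cg$distances$variant <- variant
            method_rows[[length(method_rows) + 1L]] <- cg$distances
          }
        }
      }
      if (!is.null(alerts)) {
        am <- matchAlerts(mol, alerts)
        for (meth in methods) {
          v <- per[[meth]][[1L]]   # canonical, aligned (canonical order)
          ranks <- canonicalAtomRanks(mol)
          alert_pos <- ranks[am$atoms]
          imp <- if (length(alert_pos)) {
            if (signed) sum(v@values[alert_pos]) else sum(abs(v@values[alert_pos]))
          } else 0
          alert_rows[[length(alert_rows) + 1L]] <- data.frame(
            model = mn, molecule = mol, method = meth,
            alert_importance = imp, has_alert = length(alert_pos) > 0,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  sample_distances <- do.call(rbind, sample_rows)
  method_distances <- if (length(method_rows)) do.call(rbind, method_rows) else data.frame()
  entropy_df <- do.call(rbind, entropy_rows)
  alert_df <- if (length(alert_rows)) do.call(rbind, alert_rows) else data.frame()

  summary <- list()
  if (!is.null(sample_distances)) {
    agg <- stats::aggregate(score ~ model + method, sample_distances, mean,
                            na.action = stats::na.omit)
    summary$mean_sample_distance <- agg
    if (all(c("trained", "random") %in% unique(sample_distances$model))) {
      tr <- sample_distances$score[sample_distances$model == "trained"]
      rd <- sample_distances$score[sample_distances$model == "random"]
      tr <- tr[is.finite(tr)]; rd <- rd[is.finite(rd)]
      mw <- mannWhitneyU(tr, rd)
      summary$trained_vs_random <- list(
        mean_trained = mean(tr), mean_random = mean(rd),
        mannwhitney_p = mw$p,
        overlap = .distribution_overlap(tr, rd))
    }
  }
  if (nrow(method_distances)) {
    agg2 <- stats::aggregate(distance ~ model + variant, method_distances, mean,
                             na.action = stats::na.omit)
    summary$mean_method_distance <- agg2
    for (mn in unique(agg2$model)) {
      c0 <- agg2$distance[agg2$model == mn & agg2$variant == "canonical"]
      a0 <- agg2$distance[agg2$model == mn & agg2$variant == "tta_average"]
      if (length(c0) && length(a0))
        summary[[paste0("tta_reduction_", mn)]] <- c0 - a0
    }
  }
  if (nrow(alert_df)) {
    matched <- alert_df[alert_df$has_alert, , drop = FALSE]
    if (nrow(matched))
      summary$mean_alert_importance <- stats::aggregate(
        alert_importance ~ model + method, matched, mean)
  }
  # carbon dependence on the trained model, per-molecule mean over methods
  if (!is.null(sample_distances)) {
    tr_sd <- sample_distances[sample_distances$model == names(aligned)[1], , drop = FALSE]
    per_mol <- stats::aggregate(score ~ molecule, tr_sd, mean,
                                na.action = stats::na.omit)
    cd <- carbonDependence(per_mol$score, per_mol$molecule)
    summary$carbon_spearman <- cd$spearman
  }
  list(sample_distances = sample_distances, method_distances = method_distances,
       entropy = entropy_df, alert_importance = alert_df, summary = summary)
}

## simple distribution overlap: overlapping coefficient of two histograms
.distribution_overlap <- function(a, b, bins = 20L) {
  rng <- range(c(a, b))
  if (diff(rng) == 0) return(1)
  brk <- seq(rng[1], rng[2], length.out = bins + 1L)
  ha <- tabulate(findInterval(a, brk, all.inside = TRUE), bins) / length(a)
  hb <- tabulate(findInterval(b, brk, all.inside = TRUE), bins) / length(b)
  sum(pmin(ha, hb))
}
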