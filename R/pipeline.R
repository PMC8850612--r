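#' Default pipeline configuration
#'
#' A run configuration is a plain named list, fully serialized into the
#' run manifest so any artifact is regenerable from (config, seed). Sizes
#' default to a desk-scale demonstration study (a few minutes on one CPU):
#' 25 five-word-blocked sentences, 4 subjects, a 3-layer embedding family
#' frozen at 5 checkpoints, 16 MEG channels on a 0.25 s epoch grid.
#'
#' @param seed Integer master seed.
#' @return A named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    modality = "meg",
    stimuli = list(n_sentences = 25L, n_subjects = 6L,
                   sentences_per_subject = 25L, vocab_size = 80L),
    family = list(dim = 12L, n_layers = 3L, n_steps = 5L),
    brain = list(n_channels = 16L, responsive_fraction = 0.5, snr = 2,
                 shared_noise_fraction = 0.4, epoch_step = 0.25),
    scoring = list(n_folds = 5L, n_time_samples = 10L),
    importance = list(n_trees = 300L, n_repeats = 50L, n_folds = 5L))
}

pipeline_stages <- c("simulate", "extract", "score", "ceiling", "compare",
                     "importance", "report")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic encoding study
#'
#' Executes the pipeline end to end: simulate (stimuli, embedding family
#' with planted accuracy curve, multi-subject recordings generated from
#' the deepest final-checkpoint embedding) -> extract (toy contextual and
#' visual providers over the causal context windows) -> score (brain
#' scores of every family embedding and of the visual/lexical/
#' compositional levels, per subject) -> ceiling (inter-subject noise
#' ceiling) -> compare (gains, layer profile, convergence) -> importance
#' (random-forest permutation importance over model properties) ->
#' report (group-level Wilcoxon + FDR statistics and the run manifest).
#'
#' All tables are written as TSV under `out_dir`, arrays under
#' `out_dir/arrays`, and `manifest.json` records the config, seed and an
#' md5 checksum per artifact; two runs from the same (config, seed) yield
#' identical manifests.
#'
#' @param config A configuration list (see [default_config()]) or the
#'   path of a YAML file holding one.
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "extract", "score", "ceiling", "compare", "importance",
#'   "report")`; later stages reload earlier artifacts from `out_dir` and
#'   fail with a dependency error naming the missing stage.
#' @return Invisibly, a list with the in-memory results (stimuli, family,
#'   recordings, score table, ceiling, gains, convergence, importance,
#'   group stats, manifest path).
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = pipeline_stages) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  dir.create(file.path(out_dir, "arrays"), recursive = TRUE,
             showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  need <- function(key, loader, from_stage, for_stage) {
    if (!is.null(st[[key]])) return(st[[key]])
    val <- tryCatch(loader(), error = function(e) NULL)
    if (is.null(val)) {
      stop(sprintf("dependency error: stage '%s' requires output of stage '%s'",
                   for_stage, from_stage), call. = FALSE)
    }
    st[[key]] <- val
    val
  }
  arr <- function(name) file.path(out_dir, "arrays", name)
  level_names <- c("visual", "lexical", "compositional")
  times <- seq(-0.5, 2, by = config$brain$epoch_step)

  if ("simulate" %in% stages) {
    stim <- make_stimuli(
      n_sentences = config$stimuli$n_sentences,
      n_subjects = config$stimuli$n_subjects,
      sentences_per_subject = config$stimuli$sentences_per_subject,
      vocab_size = config$stimuli$vocab_size, seed = config$seed)
    fam <- make_embedding_family(
      stim, dim = config$family$dim, n_layers = config$family$n_layers,
      n_steps = config$family$n_steps, seed = config$seed + 1L)
    generator <- fam$embeddings[[sprintf("step%02d_layer%02d",
                                         config$family$n_steps,
                                         config$family$n_layers)]]
    brain <- make_brain(
      stim, generator, n_subjects = config$stimuli$n_subjects,
      n_channels = config$brain$n_channels,
      responsive_fraction = config$brain$responsive_fraction,
      snr = config$brain$snr, modality = config$modality,
      times = times,
      shared_noise_fraction = config$brain$shared_noise_fraction,
      seed = config$seed + 2L)
    write_stimuli(stim, file.path(out_dir, "stimuli.tsv"))
    for (nm in names(fam$embeddings)) {
      write_arrays(fam$embeddings[[nm]], arr(paste0("emb_", nm)))
    }
    for (rec in brain$recordings) {
      write_arrays(rec, arr(sprintf("brain_s%02d", rec$subject_id)))
    }
    st$stimuli <- stim; st$family <- fam; st$recordings <- brain$recordings
    st$brain_truth <- brain$truth
  }

  load_stimuli <- function() read_stimuli(file.path(out_dir, "stimuli.tsv"))
  load_recordings <- function() {
    paths <- Sys.glob(arr("brain_s*.json"))
    if (length(paths) == 0) return(NULL)
    lapply(sub("\\.json$", "", paths), read_arrays)
  }
  load_family <- function() {
    paths <- Sys.glob(arr("emb_step*.json"))
    if (length(paths) == 0) return(NULL)
    embs <- lapply(sub("\\.json$", "", paths), read_arrays)
    names(embs) <- sub("^emb_", "", basename(sub("\\.json$", "", paths)))
    list(embeddings = embs)
  }

  if ("extract" %in% stages) {
    stim <- need("stimuli", load_stimuli, "simulate", "extract")
    provider <- toy_contextual_provider(dim = config$family$dim,
                                        n_layers = config$family$n_layers,
                                        seed = config$seed + 3L)
    st$extracted <- extract_activations(provider, stim)
    st$visual <- toy_visual_provider(stim, dim = config$family$dim,
                                     seed = config$seed + 4L)
    write_arrays(st$visual, arr("emb_visual"))
  }

  if ("score" %in% stages) {
    stim <- need("stimuli", load_stimuli, "simulate", "score")
    fam <- need("family", load_family, "simulate", "score")
    recs <- need("recordings", load_recordings, "simulate", "score")
    vis <- need("visual", function() read_arrays(arr("emb_visual")),
                "extract", "score")
    cv <- cv_scheme(stim, n_folds = config$scoring$n_folds)
    t_idx <- meg_time_subsample(times, config$scoring$n_time_samples)
    # one batched call per embedding: all subjects share the design side
    st$family_scores <- list()
    for (nm in names(fam$embeddings)) {
      maps <- brain_score_meg_group(fam$embeddings[[nm]], recs, stim,
                                    cv = cv, time_indices = t_idx)
      for (m in maps) {
        st$family_scores[[sprintf("%s_s%02d", nm, m$subject_id)]] <- m
      }
    }
    vis_maps <- brain_score_meg_group(vis, recs, stim, cv = cv,
                                      time_indices = t_idx)
    lex_nm <- sprintf("step%02d_layer%02d", config$family$n_steps, 0L)
    comp_nm <- sprintf("step%02d_layer%02d", config$family$n_steps,
                       config$family$n_layers)
    st$level_scores <- list()
    for (m in vis_maps) {
      sid <- m$subject_id
      st$level_scores[[sprintf("visual_s%02d", sid)]] <- m
      st$level_scores[[sprintf("lexical_s%02d", sid)]] <-
        st$family_scores[[sprintf("%s_s%02d", lex_nm, sid)]]
      st$level_scores[[sprintf("compositional_s%02d", sid)]] <-
        st$family_scores[[sprintf("%s_s%02d", comp_nm, sid)]]
    }
    for (nm in names(st$level_scores)) {
      write_arrays(st$level_scores[[nm]], arr(paste0("scores_", nm)))
    }
    st$score_table <- comparison_table(st$family_scores, time_indices = t_idx)
    write_tsv(st$score_table, file.path(out_dir, "scores.tsv"))
    level_tab <- do.call(rbind, lapply(names(st$level_scores), function(nm) {
      tibble::tibble(
        level = sub("_s[0-9]+$", "", nm),
        subject = st$level_scores[[nm]]$subject_id,
        score = average_scores(st$level_scores[[nm]], time_indices = t_idx))
    }))
    write_tsv(level_tab, file.path(out_dir, "level_scores.tsv"))
    st$level_table <- level_tab
  }

  if ("ceiling" %in% stages) {
    stim <- need("stimuli", load_stimuli, "simulate", "ceiling")
    recs <- need("recordings", load_recordings, "simulate", "ceiling")
    t_idx <- meg_time_subsample(times, config$scoring$n_time_samples)
    st$ceiling_maps <- lapply(recs, function(rec) {
      noise_ceiling(recs, rec$subject_id, stim, time_indices = t_idx)
    })
    ceil_tab <- do.call(rbind, lapply(st$ceiling_maps, function(sm) {
      tibble::tibble(subject = sm$subject_id,
                     ceiling = average_scores(sm, time_indices = t_idx))
    }))
    write_tsv(ceil_tab, file.path(out_dir, "ceiling.tsv"))
    st$ceiling_table <- ceil_tab
  }

  load_level_scores <- function() {
    paths <- Sys.glob(arr("scores_*_s*.json"))
    if (length(paths) == 0) return(NULL)
    maps <- lapply(sub("\\.json$", "", paths), read_arrays)
    names(maps) <- sub("^scores_", "", basename(sub("\\.json$", "", paths)))
    maps
  }
  load_score_table <- function() {
    p <- file.path(out_dir, "scores.tsv")
    if (!file.exists(p)) return(NULL)
    tibble::as_tibble(read.delim(p, sep = "\t"))
  }

  if ("compare" %in% stages) {
    st$level_scores <- st$level_scores %||%
      need("level_scores", load_level_scores, "score", "compare")
    st$score_table <- st$score_table %||%
      need("score_table", load_score_table, "score", "compare")
    subjects <- unique(st$score_table$subject)
    t_idx <- meg_time_subsample(times, config$scoring$n_time_samples)
    st$gains <- list(
      word_over_visual = lapply(subjects, function(s) {
        gain(st$level_scores[[sprintf("lexical_s%02d", s)]],
             st$level_scores[[sprintf("visual_s%02d", s)]])
      }),
      compositional_over_word = lapply(subjects, function(s) {
        gain(st$level_scores[[sprintf("compositional_s%02d", s)]],
             st$level_scores[[sprintf("lexical_s%02d", s)]])
      }))
    gain_tab <- do.call(rbind, lapply(names(st$gains), function(nm) {
      do.call(rbind, lapply(st$gains[[nm]], function(g) {
        tibble::tibble(contrast = nm, subject = g$subject_id,
                       delta_r = average_scores(g, time_indices = t_idx))
      }))
    }))
    write_tsv(gain_tab, file.path(out_dir, "gains.tsv"))
    st$gain_table <- gain_tab
    # convergence across checkpoints: middle layers, per subject
    mid <- middle_layers(config$family$n_layers)
    tab_mid <- st$score_table[st$score_table$layer_index %in% mid, ]
    agg <- stats::aggregate(score ~ subject + training_step + accuracy_top1,
                            data = tab_mid, FUN = mean)
    agg <- tibble::as_tibble(agg)
    st$convergence <- convergence(agg, key = "accuracy_top1")
    write_tsv(st$convergence, file.path(out_dir, "convergence.tsv"))
    st$layers <- layer_profile(st$score_table)
    write_tsv(st$layers$profile, file.path(out_dir, "layer_profile.tsv"))
  }

  if ("importance" %in% stages) {
    st$score_table <- st$score_table %||%
      need("score_table", load_score_table, "score", "importance")
    ptab <- property_table(st$score_table)
    st$importance <- fit_importance(
      ptab, n_trees = config$importance$n_trees,
      n_repeats = config$importance$n_repeats,
      n_folds = config$importance$n_folds, seed = config$seed + 5L)
    st$ranking <- rank_and_compare(st$importance$importance)
    write_tsv(st$importance$importance, file.path(out_dir, "importance.tsv"))
    write_tsv(st$ranking$ranking, file.path(out_dir, "importance_ranking.tsv"))
    write_tsv(st$ranking$pairs, file.path(out_dir, "importance_pairs.tsv"))
  }

  if ("report" %in% stages) {
    if (is.null(st$gains)) {
      # rebuild the per-subject gain maps from the stored level score maps
      lv <- load_level_scores()
      tab <- load_score_table()
      if (is.null(lv) || is.null(tab)) {
        stop("dependency error: stage 'report' requires output of stage 'compare'",
             call. = FALSE)
      }
      subjects <- unique(tab$subject)
      st$gains <- list(
        compositional_over_word = lapply(subjects, function(s) {
          gain(lv[[sprintf("compositional_s%02d", s)]],
               lv[[sprintf("lexical_s%02d", s)]])
        }))
    }
    grp <- group_map(st$gains$compositional_over_word)
    write_tsv(grp, file.path(out_dir, "group_gain_compositional.tsv"))
    st$group_gain <- grp
    files <- sort(c(Sys.glob(file.path(out_dir, "*.tsv")),
                    Sys.glob(file.path(out_dir, "arrays", "*"))))
    md5 <- tools::md5sum(files)
    manifest <- list(package = "brainscore",
                     version = as.character(utils::packageVersion("brainscore")),
                     seed = config$seed, config = config,
                     files = as.list(setNames(
                       unname(md5),
                       substring(files, nchar(out_dir) + 2L))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    st$manifest <- file.path(out_dir, "manifest.json")
  }
  invisible(as.list(st))
}
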