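# End-to-end pipeline: simulate -> preprocess -> lexicon -> emotions ->
# intensity -> transitions -> topics -> gsom -> stats, driven by one config.

#' Default four-phase scenarios for the synthetic generator
#'
#' Windows follow the literal month boundaries of the four 2020 pandemic
#' phases. The two lockdown emotion mixtures are the published normalized
#' intensity columns (divided by 100); the prepandemic and easing mixtures
#' encode the narrative pattern (sadness/fear dominant early, joy highest
#' while restrictions ease). Each phase also carries a generating transition
#' matrix with emotion inertia: `P = 0.4 I + 0.6 * mixture` row-wise.
#'
#' @param n_posts_per_phase Posts per phase (recycled to length 4).
#' @return List of four `phase_scenario`s.
#' @export
default_scenarios <- function(n_posts_per_phase = 1000) {
  n <- rep_len(n_posts_per_phase, 4)
  emo <- plutchik_emotions()
  mixes <- list(
    prepandemic = c(anger = 0.08, sadness = 0.30, disgust = 0.05,
                    fear = 0.25, joy = 0.12, surprise = 0.05,
                    trust = 0.08, anticipation = 0.07),
    first_lockdown = c(anger = 0.1384, sadness = 0.3136, disgust = 0.0981,
                       fear = 0.1758, joy = 0.1694, surprise = 0.0132,
                       trust = 0.0656, anticipation = 0.0259),
    easing_restrictions = c(anger = 0.08, sadness = 0.18, disgust = 0.05,
                            fear = 0.12, joy = 0.25, surprise = 0.08,
                            trust = 0.12, anticipation = 0.12),
    second_lockdown = c(anger = 0.1597, sadness = 0.3101, disgust = 0.1206,
                        fear = 0.1966, joy = 0.1256, surprise = 0.0074,
                        trust = 0.0563, anticipation = 0.0237))
  topic_mixes <- list(
    prepandemic = c(lockdown_policy = 0.2, health = 0.4, economy = 0.2,
                    education = 0.2),
    first_lockdown = c(lockdown_policy = 0.35, health = 0.2, economy = 0.25,
                       education = 0.2),
    easing_restrictions = c(lockdown_policy = 0.4, health = 0.2,
                            economy = 0.25, education = 0.15),
    second_lockdown = c(lockdown_policy = 0.3, health = 0.35, economy = 0.2,
                        education = 0.15))
  win <- default_phase_windows()
  lapply(seq_len(4), function(i) {
    mix <- mixes[[win$name[i]]][emo]
    P <- 0.4 * diag(8) + 0.6 * matrix(mix, 8, 8, byrow = TRUE)
    phase_scenario(win$name[i], c(win$start[i], win$end[i]),
                   emotion_mixture = mix,
                   topic_mixture = topic_mixes[[win$name[i]]],
                   n_posts = n[i], transition_matrix = P)
  })
}

#' Path of the bundled demo pipeline configuration
#'
#' @return File path to the packaged YAML config.
#' @export
demo_config_path <- function() {
  system.file("extdata", "demo_config.yaml", package = "emovista")
}

#' Run the full pipeline from a single configuration
#'
#' Stages run in order: simulate (or load a JSON-lines corpus), preprocess,
#' embedding + lexicon expansion, emotion scoring, per-phase intensity
#' profiles, transition models, topic models with cross-phase association,
#' GSOM behavior profiles, and the two-lockdown statistical comparison.
#' All randomness derives from the named seeds in the config, so an
#' identical config yields identical outputs. Module outputs are written as
#' CSV/JSONL/DOT under `out_dir` together with a run manifest (parameters
#' plus a content hash per file).
#'
#' @param config A nested list or the path of a YAML file. Required: either
#'   `input` (corpus JSONL path) or a `simulate` block. Optional blocks:
#'   `preprocess`, `embedding`, `lexicon`, `emotions`, `topics`, `gsom`,
#'   `compare`; `seed` is the master seed.
#' @param out_dir Output directory (created if missing); overrides
#'   `config$out_dir`.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("validation error: no output directory configured")
  if (is.null(config$input) && is.null(config$simulate)) {
    stop("validation error: config needs an `input` corpus or a `simulate` block")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cfg <- function(block, key, default) {
    v <- config[[block]][[key]]
    if (is.null(v)) default else v
  }
  log_stage <- function(...) message(sprintf(...))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  outputs <- character(0)
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  # --- corpus -------------------------------------------------------------
  corpus <- run_stage("simulate", {
    if (!is.null(config$input)) {
      list(posts = read_corpus_jsonl(config$input), ground_truth = NULL)
    } else {
      vocab <- build_default_vocabulary()
      scen <- default_scenarios(cfg("simulate", "n_posts_per_phase", 800))
      generate_corpus(vocab, scen,
                      n_users = cfg("simulate", "n_users", 150),
                      bot_fraction = cfg("simulate", "bot_fraction", 0.02),
                      negation_prob = cfg("simulate", "negation_prob", 0.1),
                      seed = seed)
    }
  })
  log_stage("simulate: %d posts", nrow(corpus$posts))
  corpus_path <- file.path(out_dir, "corpus.jsonl")
  write_corpus_jsonl(corpus$posts, corpus_path)
  outputs <- c(outputs, corpus_path)

  # --- preprocess ---------------------------------------------------------
  prep <- run_stage("preprocess", {
    preprocess_corpus(corpus$posts,
                      volume_percentile = cfg("preprocess", "bot_percentile", 0.99),
                      dup_threshold = cfg("preprocess", "dup_threshold", 1),
                      salt = cfg("preprocess", "salt", "emovista"))
  })
  log_stage("preprocess: %d posts kept, %d users removed by volume filter",
            nrow(prep$posts), length(prep$removed_users))

  # --- lexicon ------------------------------------------------------------
  model <- run_stage("lexicon", {
    train_embeddings(prep$posts$clean_tokens,
                     d = cfg("embedding", "d", 100),
                     window = cfg("embedding", "window", 5),
                     min_count = cfg("embedding", "min_count", 3),
                     epochs = cfg("embedding", "epochs", 10),
                     seed = seed)
  })
  lexicon <- run_stage("lexicon", {
    expand_lexicons(model, k = cfg("lexicon", "k", 20),
                    tau = cfg("lexicon", "tau", 0.35))
  })
  log_stage("lexicon: %d terms (%d expanded)", nrow(lexicon),
            sum(lexicon$provenance == "expanded"))
  lex_path <- file.path(out_dir, "lexicon.tsv")
  write_lexicon_tsv(lexicon, lex_path)
  outputs <- c(outputs, lex_path)

  # --- emotions -----------------------------------------------------------
  scored <- run_stage("emotions", {
    sc <- score_posts(prep$posts, lexicon,
                      window = cfg("emotions", "window", 3))
    sc$user_id <- prep$posts$user_id
    sc
  })
  emit(scored[, c("post_id", "phase", plutchik_emotions(), "dominant")],
       "emotions.csv")
  sequences <- build_sequences(scored)
  log_stage("emotions: %d scored posts, %d sequences", nrow(scored),
            nrow(sequences))

  # --- intensity ----------------------------------------------------------
  phases <- unique(scored$phase)
  profiles <- run_stage("intensity", {
    setNames(lapply(phases, function(ph) phase_intensity_profile(scored, ph)),
             phases)
  })
  emit(intensity_table(profiles), "intensity.csv")

  # --- transitions --------------------------------------------------------
  tmodels <- run_stage("transitions", {
    setNames(lapply(phases, function(ph) {
      estimate_transition_model(sequences, phase = ph)
    }), phases)
  })
  for (ph in phases) {
    emit(as.data.frame(tmodels[[ph]]$P), paste0("transitions_", ph, ".csv"))
    dot <- file.path(out_dir, paste0("transitions_", ph, ".dot"))
    write_transition_dot(tmodels[[ph]], dot)
    outputs <- c(outputs, dot)
  }
  emit(do.call(rbind, lapply(phases, function(ph) {
    tt <- top_transitions(tmodels[[ph]], 5)
    tt$phase <- ph
    tt
  })), "top_transitions.csv")

  # --- topics -------------------------------------------------------------
  Kcfg <- cfg("topics", "k", 4)
  topic_models <- run_stage("topics", {
    setNames(lapply(phases, function(ph) {
      docs <- prep$posts$clean_tokens[prep$posts$phase == ph]
      K <- if (identical(Kcfg, "auto")) {
        select_topic_count(docs, seed = seed)
      } else {
        as.integer(Kcfg)
      }
      fit_topics(docs, K, seed = seed, iters = cfg("topics", "iters", 200),
                 phase = ph)
    }), phases)
  })
  emit(do.call(rbind, lapply(topic_models, topic_table)), "topics.csv")
  assoc <- run_stage("topics", {
    associate_topics(unname(topic_models), model,
                     threshold = cfg("topics", "assoc_threshold", 0.5))
  })
  emit(assoc$edges, "topic_associations.csv")

  # --- gsom ---------------------------------------------------------------
  gsom_res <- run_stage("gsom", {
    ph_g <- cfg("gsom", "phase", phases[length(phases)])
    tm <- topic_models[[ph_g]]
    in_phase <- which(prep$posts$phase == ph_g)
    td <- tibble::tibble(user_id = prep$posts$user_id[in_phase[tm$doc_topic$doc]],
                         dominant_topic = tm$doc_topic$dominant_topic)
    feats <- user_feature_vectors(scored[scored$phase == ph_g, ], td, tm$K)
    cfg_g <- gsom_config(sf = cfg("gsom", "sf", 0.3),
                         alpha0 = cfg("gsom", "alpha0", 0.3),
                         fd = cfg("gsom", "fd", 0.5),
                         growth_epochs = cfg("gsom", "growth_epochs", 30),
                         smooth_epochs = cfg("gsom", "smooth_epochs", 30),
                         neighborhood0 = cfg("gsom", "neighborhood0", 3),
                         seed = seed)
    map <- train_gsom(feats, cfg_g)
    prof <- derive_profiles(map, feats,
                            min_hits = cfg("gsom", "min_hits", 2))
    list(map = map, profiles = prof, features = feats, phase = ph_g)
  })
  emit(do.call(rbind, lapply(seq_len(nrow(gsom_res$profiles$profiles)),
    function(p) {
      mv <- gsom_res$profiles$mean_vectors[[p]]
      tibble::tibble(profile_id = p,
                     label = gsom_res$profiles$profiles$label[p],
                     n_users = gsom_res$profiles$profiles$n_members[p],
                     feature = names(mv), mean_strength = unname(mv))
    })), "profiles.csv")
  log_stage("gsom: %d nodes, %d profiles on phase %s",
            nrow(gsom_res$map$coords), nrow(gsom_res$profiles$profiles),
            gsom_res$phase)

  # --- stats --------------------------------------------------------------
  cmp <- run_stage("stats", {
    a <- cfg("compare", "a", "first_lockdown")
    b <- cfg("compare", "b", "second_lockdown")
    compare_intensity_profiles(profiles[[a]], profiles[[b]])
  })
  emit(cmp, "comparison.csv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("emovista")),
    seed = seed,
    parameters = config,
    files = lapply(setNames(nm = basename(outputs)), function(f) {
      salted_hash(paste(readLines(file.path(out_dir, f), warn = FALSE),
                        collapse = "\n"), salt = "manifest")
    }))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(corpus = corpus, preprocessed = prep, embedding = model,
                 lexicon = lexicon, scored = scored, sequences = sequences,
                 intensity = profiles, transitions = tmodels,
                 topics = topic_models, association = assoc, gsom = gsom_res,
                 comparison = cmp, manifest = manifest))
}
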