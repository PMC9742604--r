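#' Configure the full network-construction model
#'
#' Bundles the configurations of the generator front end (region-guided 3D
#' CNN), the attention refiner, the Gaussian-kernel connectivity layer, the
#' per-ROI discriminator and the graph convolutional classifier. At full
#' brain scale the defaults are 4 conv blocks with channels (8, 16, 32, 64)
#' and 11 attention heads; small phantoms use fewer blocks and heads.
#'
#' @param grid length-3 spatial grid dimensions.
#' @param n_roi number of ROIs.
#' @param n_time number of time points.
#' @param heads attention heads.
#' @param n_blocks convolutional blocks.
#' @param channels channels per block.
#' @param classes character vector of class labels (the second label is, by
#'   package convention, the "positive"/later-stage group).
#' @param sigma Gaussian kernel bandwidth (default 2).
#' @return an `fbn_config` list.
#' @export
fbn_config <- function(grid, n_roi, n_time, heads = 11L, n_blocks = 4L,
                       channels = c(8L, 16L, 32L, 64L)[seq_len(n_blocks)],
                       classes = c("A", "B"), sigma = 2) {
  structure(list(
    cnn = region_cnn_config(grid, n_roi, n_time, n_blocks, channels),
    sat = sat_config(n_roi, n_time, heads),
    n_roi = as.integer(n_roi), n_time = as.integer(n_time),
    classes = classes, n_classes = length(classes), sigma = sigma),
    class = "fbn_config")
}

#' Configuration matched to a phantom spec
#'
#' @param spec a [phantom_spec()].
#' @param heads attention heads.
#' @param n_blocks convolutional blocks.
#' @return an `fbn_config`.
#' @export
fbn_config_for_spec <- function(spec, heads = 4L, n_blocks = 2L) {
  fbn_config(spec$grid, spec$n_roi, spec$n_time, heads = heads,
             n_blocks = n_blocks, classes = spec$classes)
}

#' Initialize model parameters
#'
#' All weights are drawn from seeded Gaussians (He/Glorot scaling); the
#' kernel transform starts at identity plus small noise (sd 0.01) so the
#' connectivity layer begins near a plain Gaussian-distance kernel.
#'
#' @param config an [fbn_config()].
#' @param seed integer seed.
#' @return an object of class `fbn_model`.
#' @export
fbn_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "fbn_config"))
  q <- config$n_time
  params <- with_seed(seed, list(
    cnn = region_cnn_init(config$cnn),
    sat = sat_init(config$sat),
    clw = diag(q) + matrix(rnorm(q * q, sd = 0.01), q, q),
    mtd = mtd_init(config$n_roi, q),
    gcn = gcn_init(config$n_roi, q, config$n_classes)))
  structure(list(config = config, params = params,
                 stats = region_cnn_stats_init(config$cnn),
                 seed = as.integer(seed)),
            class = "fbn_model")
}

#' @export
print.fbn_model <- function(x, ...) {
  cfg <- x$config
  np <- function(p) if (is.list(p)) sum(vapply(p, np, 0)) else length(p)
  cat("adversarial FBN model:", cfg$n_roi, "ROIs x", cfg$n_time, "frames,",
      cfg$cnn$n_blocks, "conv blocks,", cfg$sat$heads, "heads,",
      format(np(x$params), big.mark = ","), "parameters\n")
  invisible(x)
}

# Full generator forward: rough CNN features then attention refinement.
generator_fwd <- function(volume, emb, model, train = TRUE) {
  cnn <- region_cnn_fwd(volume, emb, model$params$cnn, model$stats,
                        model$config$cnn, train = train)
  sat <- sat_fwd(cnn$f1, emb, model$params$sat, model$config$sat)
  list(f1 = cnn$f1, fg = sat$fg,
       cnn_cache = cnn$cache, sat_cache = sat$cache, stats = cnn$stats)
}

generator_bwd <- function(dfg, fwd, model) {
  satb <- sat_bwd(dfg, fwd$sat_cache, model$params$sat, model$config$sat)
  cnng <- region_cnn_bwd(satb$df1, fwd$cnn_cache, model$params$cnn,
                         model$config$cnn)
  list(cnn = cnng, sat = satb$grads)
}

#' Construct ROI series and a functional network from a 4D volume
#'
#' Runs the trained generator in evaluation mode (batch-norm running
#' statistics) and maps the generated series through the learned Gaussian
#' kernel.
#'
#' @param model a trained [fbn_model()].
#' @param volume 4D fMRI array (X, Y, Z, T).
#' @param atlas atlas `data.frame` matching the model's ROI count.
#' @return list with `series` (generated `n_roi` x `n_time` matrix) and
#'   `fc` (generated symmetric connectivity matrix, unit diagonal).
#' @export
construct_fbn <- function(model, volume, atlas) {
  stopifnot(inherits(model, "fbn_model"))
  emb <- normalize_embeddings(atlas)
  fwd <- generator_fwd(volume, emb, model, train = FALSE)
  fg <- fwd$fg
  rownames(fg) <- atlas$name
  list(series = fg,
       fc = gaussian_connectivity(fg, model$params$clw, model$config$sigma))
}

# Classifier probabilities for one subject. `path` selects which
# (network, series) pair feeds the classifier; "both" averages the two
# predictive distributions. `shield` zeroes one ROI's series row and
# connectivity row/column (diagonal kept 1) before classification.
predict_subject <- function(model, subject, emb, path = "both",
                            shield = NULL, gen = NULL) {
  probs <- NULL
  apply_shield <- function(f, a, i) {
    f[i, ] <- 0
    a[i, ] <- 0; a[, i] <- 0; diag(a) <- 1
    list(f = f, a = a)
  }
  if (path %in% c("both", "generated")) {
    if (is.null(gen)) {
      if (is.null(subject$volume))
        stop("generated-path prediction needs the subject volume", call. = FALSE)
      fwd <- generator_fwd(subject$volume, emb, model, train = FALSE)
      fg <- fwd$fg
      ag <- gaussian_connectivity(fg, model$params$clw, model$config$sigma)
    } else {
      fg <- gen$series; ag <- gen$fc
    }
    if (!is.null(shield)) {
      sh <- apply_shield(fg, ag, shield); fg <- sh$f; ag <- sh$a
    }
    pg <- gcn_forward(normalize_adjacency(ag), fg, model$params$gcn)$probs
    probs <- rbind(probs, pg)
  }
  if (path %in% c("both", "empirical")) {
    fe <- subject$series_emp
    ae <- subject$fc_emp
    if (!is.null(shield)) {
      sh <- apply_shield(fe, ae, shield); fe <- sh$f; ae <- sh$a
    }
    pe <- gcn_forward(normalize_adjacency(ae, empirical = TRUE), fe,
                      model$params$gcn)$probs
    probs <- rbind(probs, pe)
  }
  setNames(colMeans(probs), model$config$classes)
}

#' Predict class probabilities for a set of subjects
#'
#' @param model a trained `fbn_model`.
#' @param subjects list of subjects (as in a `phantom_study`) or a
#'   `phantom_study`.
#' @param path `"both"` (default; average of generated-path and
#'   empirical-path predictive distributions), `"generated"`, or
#'   `"empirical"`.
#' @param shield optional ROI index whose series row and connectivity
#'   row/column are zeroed before classification.
#' @return data.frame with subject id, true class (if known), predicted
#'   class, and one probability column per class.
#' @export
predict_study <- function(model, subjects, path = "both", shield = NULL) {
  if (inherits(subjects, "phantom_study")) {
    emb <- subjects$emb
    subjects <- subjects$subjects
  } else {
    emb <- attr(subjects, "emb")
    if (is.null(emb)) stop("supply a phantom_study or subjects with an 'emb' attribute",
                           call. = FALSE)
  }
  path <- match.arg(path, c("both", "generated", "empirical"))
  probs <- t(vapply(subjects,
                    function(s) predict_subject(model, s, emb, path, shield),
                    numeric(model$config$n_classes)))
  cls <- model$config$classes
  data.frame(
    id = vapply(subjects, function(s) s$id %||% NA_character_, ""),
    class = vapply(subjects, function(s) s$class %||% NA_character_, ""),
    predicted = cls[max.col(probs, ties.method = "first")],
    probs, check.names = FALSE, stringsAsFactors = FALSE)
}
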