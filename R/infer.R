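# Pluggable bootstrap ensemble inference. The baseline method is a
# documented stand-in for published bootstrap network-inference pipelines:
# it resamples whole experiment sets, regresses finite-difference
# derivative estimates on log-transformed expression, and includes a
# regulation when the standardized coefficient magnitude clears a
# threshold. It makes no claim to reproduce any specific published
# inference engine.

.inferenceRegistry <- new.env(parent = emptyenv())

#' Register an ensemble-inference method
#'
#' A method is a function(data, config, mask) returning a list of
#' \code{config@ng} \linkS4class{DirectedNetwork} objects over the data's
#' genes. Masks are additionally enforced centrally by
#' \code{\link{inferEnsemble}}.
#'
#' @param name method name
#' @param fun the method function
#' @export
registerInferenceMethod <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .inferenceRegistry)
  invisible(name)
}

#' Names of the registered inference methods
#' @export
listInferenceMethods <- function() sort(ls(.inferenceRegistry))

#' Construct an inference configuration
#'
#' @param ng number of bootstrap networks.
#' @param method registered method name.
#' @param threshold standardized-coefficient inclusion threshold of the
#'   baseline method.
#' @param seed RNG seed (NA leaves the RNG state untouched).
#' @return an \linkS4class{InferenceConfig}
#' @export
InferenceConfig <- function(ng = 100L, method = "baseline", threshold = 0.3,
                            seed = NA_integer_) {
  obj <- new("InferenceConfig", ng = as.integer(ng), method = method,
             threshold = threshold, seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Construct a prior-knowledge mask
#'
#' @param forbidden,forced two-column matrices or data.frames of
#'   (regulator, target) pairs; disjoint.
#' @return a \linkS4class{PriorKnowledgeMask}
#' @export
PriorKnowledgeMask <- function(forbidden = NULL, forced = NULL) {
  obj <- new("PriorKnowledgeMask",
             forbidden = .asPairMatrix(forbidden, "forbidden"),
             forced = .asPairMatrix(forced, "forced"))
  validObject(obj)
  obj
}

#' Read a mask file
#'
#' TSV with columns regulator, target, action where action is one of
#' \code{forbid}, \code{force} or \code{allow} (allow lines are ignored).
#'
#' @param path file path
#' @return a \linkS4class{PriorKnowledgeMask}
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  tab <- read.table(path, colClasses = "character",
                    col.names = c("regulator", "target", "action"))
  act <- tolower(tab$action)
  bad <- setdiff(unique(act), c("forbid", "force", "allow"))
  if (length(bad)) stop("unknown mask action(s): ", paste(bad, collapse = ", "))
  PriorKnowledgeMask(forbidden = tab[act == "forbid", 1:2],
                     forced = tab[act == "force", 1:2])
}

.applyMask <- function(net, mask) {
  if (is.null(mask)) return(net)
  r <- net@regulations
  if (nrow(mask@forbidden)) {
    keep <- !(.pairKey(r[, 1L], r[, 2L]) %in%
                .pairKey(mask@forbidden[, 1L], mask@forbidden[, 2L]))
    r <- r[keep, , drop = FALSE]
  }
  if (nrow(mask@forced)) r <- rbind(r, mask@forced)
  DirectedNetwork(net@genes, r)
}

#' Infer an ensemble of directed networks from time-series data
#'
#' Dispatches to the registered method named in the configuration, then
#' enforces the prior-knowledge mask: no forbidden regulation appears in
#' any returned network and every forced regulation appears in all.
#'
#' @param data a non-empty \linkS4class{TimeSeriesSet}
#' @param config an \linkS4class{InferenceConfig}
#' @param mask optional \linkS4class{PriorKnowledgeMask}
#' @return list of \code{config@ng} \linkS4class{DirectedNetwork}
#' @export
inferEnsemble <- function(data, config = InferenceConfig(), mask = NULL) {
  stopifnot(is(data, "TimeSeriesSet"))
  if (dim(data@clean)[1L] < 1L) stop("time-series data is empty")
  if (!exists(config@method, envir = .inferenceRegistry, inherits = FALSE))
    stop("unknown inference method '", config@method, "'; registered: ",
         paste(listInferenceMethods(), collapse = ", "))
  fun <- get(config@method, envir = .inferenceRegistry)
  if (!is.na(config@seed)) set.seed(config@seed)
  nets <- fun(data, config, mask)
  if (length(nets) != config@ng)
    stop("method '", config@method, "' returned ", length(nets),
         " networks instead of ", config@ng)
  lapply(nets, .applyMask, mask = mask)
}

#' Finite-difference derivative estimates
#'
#' Central differences at interior timepoints, one-sided differences at the
#' ends, per experiment set and gene, computed from the noisy observations.
#'
#' @param data a \linkS4class{TimeSeriesSet}
#' @return array with the same sets x times x genes shape as the data
#' @export
estimateDerivatives <- function(data) {
  X <- data@noisy
  tt <- data@times
  Tn <- length(tt)
  if (Tn < 2L) stop("derivative estimation needs at least 2 timepoints")
  D <- array(NA_real_, dim = dim(X), dimnames = dimnames(X))
  D[, 1L, ] <- (X[, 2L, ] - X[, 1L, ]) / (tt[2L] - tt[1L])
  D[, Tn, ] <- (X[, Tn, ] - X[, Tn - 1L, ]) / (tt[Tn] - tt[Tn - 1L])
  if (Tn > 2L) {
    for (k in 2:(Tn - 1L)) {
      D[, k, ] <- (X[, k + 1L, ] - X[, k - 1L, ]) / (tt[k + 1L] - tt[k - 1L])
    }
  }
  D
}

#' Baseline bootstrap regression inference
#'
#' For each bootstrap replicate the experiment sets are resampled with
#' replacement (whole sets, preserving within-set dynamics). Derivatives
#' are estimated by finite differences and, for each target gene, regressed
#' on the log-transformed expression of all non-forbidden candidate
#' regulators (including the gene itself, so auto-degradation can surface
#' as an auto-regulation). A regulation enters the replicate's network when
#' its standardized regression coefficient magnitude exceeds
#' \code{config@threshold}. Constant regressors are dropped with a warning.
#'
#' @param data a \linkS4class{TimeSeriesSet} with at least 2 timepoints
#' @param config an \linkS4class{InferenceConfig}
#' @param mask optional \linkS4class{PriorKnowledgeMask} (forbidden pairs
#'   are excluded from the candidate set; forced pairs are added by
#'   \code{\link{inferEnsemble}})
#' @return list of \code{config@ng} \linkS4class{DirectedNetwork}
#' @export
baselineBootstrapRegression <- function(data, config = InferenceConfig(),
                                        mask = NULL) {
  gl <- data@genes
  N <- length(gl)
  S <- dim(data@noisy)[1L]
  D <- estimateDerivatives(data)
  logX <- log(pmax(data@noisy, 1e-6))
  logXBySet <- lapply(seq_len(S), function(s) logX[s, , , drop = TRUE])
  dBySet <- lapply(seq_len(S), function(s) D[s, , , drop = TRUE])

  forbiddenKey <- if (!is.null(mask) && nrow(mask@forbidden)) {
    .pairKey(mask@forbidden[, 1L], mask@forbidden[, 2L])
  } else character()

  warnedConstant <- FALSE
  nets <- vector("list", config@ng)
  for (b in seq_len(config@ng)) {
    pick <- floor(runif(S) * S) + 1L
    Xb <- do.call(rbind, logXBySet[pick])
    Db <- do.call(rbind, dBySet[pick])
    reg <- matrix(character(), 0L, 2L)
    for (n in seq_len(N)) {
      cand <- seq_len(N)
      if (length(forbiddenKey)) {
        cand <- cand[!(.pairKey(gl[cand], gl[n]) %in% forbiddenKey)]
      }
      if (!length(cand)) next
      Xc <- Xb[, cand, drop = FALSE]
      sds <- apply(Xc, 2L, sd)
      if (any(sds == 0)) {
        if (!warnedConstant) {
          warning("constant regressor(s) dropped from the bootstrap design")
          warnedConstant <- TRUE
        }
        cand <- cand[sds > 0]
        Xc <- Xb[, cand, drop = FALSE]
        if (!length(cand)) next
      }
      y <- Db[, n]
      sy <- sd(y)
      if (sy == 0) next
      ys <- (y - mean(y)) / sy
      Xs <- scale(Xc)
      beta <- stats::lm.fit(cbind(1, Xs), ys)$coefficients[-1L]
      beta[is.na(beta)] <- 0
      sel <- cand[abs(beta) > config@threshold]
      if (length(sel)) reg <- rbind(reg, cbind(gl[sel], gl[n]))
    }
    nets[[b]] <- DirectedNetwork(gl, reg)
  }
  nets
}

# registry entries are created at load time so the installed namespace is
# ready to dispatch
.onLoad <- function(libname, pkgname) {
  registerInferenceMethod("baseline", baselineBootstrapRegression)
}
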