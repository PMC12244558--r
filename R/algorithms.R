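#' Available SDM algorithm adapters
#'
#' Each adapter wraps one learner behind a common contract: `fit(X, y, seed)`
#' returns a fitted object and `predict(fit, X)` returns suitabilities in
#' `[0, 1]`, deterministic under a fixed seed. Classification-family
#' adapters weight classes inversely to their frequency so unequal
#' presence/pseudo-absence counts do not bias the decision surface.
#'
#' Shipped adapters: `CTA` (single classification tree, Gini splits), `RF`
#' (random forest, 500 trees), `SVM` (RBF-kernel support vector machine with
#' probability outputs), `GLM` (logistic regression with linear + quadratic
#' terms), `GBM` (gradient-boosted trees: 1000 rounds, learning rate 0.01,
#' depth 3; needs the xgboost package), `GAM` (thin-plate smooths via mgcv)
#' and `ANN` (single-hidden-layer network via nnet). The final shipped
#' ensemble uses CTA, RF and SVM.
#'
#' @return `sdm_algorithms()` returns the character vector of adapter names.
#' @export
sdm_algorithms <- function() {
  c("CTA", "RF", "SVM", "GLM", "GBM", "GAM", "ANN")
}

class_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  w <- sum(tab) / (2 * pmax(tab, 1))
  stats::setNames(as.numeric(w), names(tab))
}

clamp01 <- function(p) pmin(1, pmax(0, as.numeric(p)))

# Internal adapter registry. X: numeric matrix/data.frame (rows = cells),
# y: 0/1 integer vector.
sdm_adapter <- function(name) {
  name <- toupper(name)
  adapters <- list(
    CTA = list(
      fit = function(X, y, seed) {
        df <- data.frame(.y = factor(y, levels = c(0, 1)), X)
        w <- class_weights(y)[as.character(y)]
        local_seed(seed, rpart::rpart(
          .y ~ ., data = df, weights = as.numeric(w), method = "class",
          control = rpart::rpart.control(cp = 0.001, minbucket = 5, maxdepth = 30)
        ))
      },
      predict = function(fit, X) {
        clamp01(stats::predict(fit, data.frame(X), type = "prob")[, "1"])
      }
    ),
    RF = list(
      fit = function(X, y, seed) {
        local_seed(seed, randomForest::randomForest(
          x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
          ntree = 500, classwt = class_weights(y)
        ))
      },
      predict = function(fit, X) {
        clamp01(stats::predict(fit, as.data.frame(X), type = "prob")[, "1"])
      }
    ),
    SVM = list(
      fit = function(X, y, seed) {
        local_seed(seed, e1071::svm(
          x = as.matrix(X), y = factor(y, levels = c(0, 1)),
          kernel = "radial", probability = TRUE,
          class.weights = class_weights(y)
        ))
      },
      predict = function(fit, X) {
        p <- stats::predict(fit, as.matrix(X), probability = TRUE)
        clamp01(attr(p, "probabilities")[, "1"])
      }
    ),
    GLM = list(
      fit = function(X, y, seed) {
        X <- as.matrix(X)
        Xq <- cbind(X, X^2)
        colnames(Xq) <- c(colnames(X), paste0(colnames(X), "_sq"))
        df <- data.frame(.y = y, Xq)
        suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      },
      predict = function(fit, X) {
        X <- as.matrix(X)
        Xq <- cbind(X, X^2)
        colnames(Xq) <- c(colnames(X), paste0(colnames(X), "_sq"))
        clamp01(stats::predict(fit, data.frame(Xq), type = "response"))
      }
    ),
    GBM = list(
      fit = function(X, y, seed) {
        if (!requireNamespace("xgboost", quietly = TRUE)) {
          stop("the GBM adapter needs the xgboost package", call. = FALSE)
        }
        w <- class_weights(y)
        dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = 0.01,
                        max_depth = 3,
                        scale_pos_weight = w[["1"]] / w[["0"]],
                        nthread = 1),
          data = dtrain, nrounds = 1000, verbose = 0
        )
      },
      predict = function(fit, X) {
        clamp01(stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(X))))
      }
    ),
    GAM = list(
      fit = function(X, y, seed) {
        if (!requireNamespace("mgcv", quietly = TRUE)) {
          stop("the GAM adapter needs the mgcv package", call. = FALSE)
        }
        df <- data.frame(.y = y, X)
        k <- max(3, min(5, floor(length(y) / (2 * ncol(X)))))
        terms <- paste(sprintf("s(%s, k = %d)", colnames(X), k), collapse = " + ")
        suppressWarnings(mgcv::gam(
          stats::as.formula(paste(".y ~", terms)), data = df,
          family = stats::binomial(), method = "REML"
        ))
      },
      predict = function(fit, X) {
        clamp01(stats::predict(fit, data.frame(X), type = "response"))
      }
    ),
    ANN = list(
      fit = function(X, y, seed) {
        if (!requireNamespace("nnet", quietly = TRUE)) {
          stop("the ANN adapter needs the nnet package", call. = FALSE)
        }
        Xs <- scale(as.matrix(X))
        ctr <- attr(Xs, "scaled:center")
        scl <- attr(Xs, "scaled:scale")
        scl[scl == 0] <- 1
        fit <- local_seed(seed, nnet::nnet(
          x = sweep(sweep(as.matrix(X), 2, ctr), 2, scl, "/"), y = y,
          size = 5, decay = 0.01, maxit = 500, entropy = TRUE, trace = FALSE
        ))
        list(net = fit, center = ctr, scale = scl)
      },
      predict = function(fit, X) {
        Xs <- sweep(sweep(as.matrix(X), 2, fit$center), 2, fit$scale, "/")
        clamp01(stats::predict(fit$net, Xs))
      }
    )
  )
  if (!name %in% names(adapters)) {
    stop(sprintf("unknown algorithm '%s'; available: %s", name,
                 paste(names(adapters), collapse = ", ")), call. = FALSE)
  }
  adapters[[name]]
}
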