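## Continuous-time Markov models of gene gain/loss/duplication.
##
## State spaces: binary models B1, B2 act on {0, 1}; three-state models
## M1, M2 act on {0, 1, m} (absent, single copy, multiple in-paralogs).
## Fixed state order: ("0", "1") and ("0", "1", "m").

.MODEL_PARAMS <- list(
    B1 = "c",
    B2 = c("g", "l"),
    M1 = c("g1", "g2", "l1", "l2", "c"),
    M2 = c("g1", "g2", "l1", "l2", "c1", "c2")
)

.BINARY_STATES <- c("0", "1")
.TERNARY_STATES <- c("0", "1", "m")

#' Rate model for gene gain, loss and duplication
#'
#' An S4 class holding one of the four gain/loss models and its rate
#' parameters. The models are continuous-time Markov chains on gene
#' states: the binary models \code{B1} (one symmetric rate \code{c}) and
#' \code{B2} (gain \code{g}: 0 to 1, loss \code{l}: 1 to 0), and the
#' three-state models \code{M1}/\code{M2} on states absent (0), single
#' copy (1), multiple in-paralogs (m) with rates \code{g1} (0 to 1),
#' \code{g2} (1 to m, duplication), \code{l1} (1 to 0), \code{l2}
#' (m to 1), and direct-jump rates \code{c1} (0 to m) and \code{c2}
#' (m to 0, loss of all copies at once). In \code{M1} the direct-jump
#' rates are tied, \code{c1 = c2 = c}.
#'
#' @slot model One of \code{"B1"}, \code{"B2"}, \code{"M1"}, \code{"M2"}.
#' @slot rates Named numeric vector of nonnegative rates; the required
#'   names depend on the model (see above).
#'
#' @seealso [rateMatrix()], [transitionMatrix()], [stationaryDistribution()]
#' @export
setClass("RateModel",
    representation(model = "character", rates = "numeric"))

setValidity("RateModel", function(object) {
    if (length(object@model) != 1L ||
        !object@model %in% names(.MODEL_PARAMS))
        return("model must be one of B1, B2, M1, M2")
    want <- .MODEL_PARAMS[[object@model]]
    if (!setequal(names(object@rates), want) ||
        length(object@rates) != length(want))
        return(sprintf("model %s requires rates named: %s",
                       object@model, paste(want, collapse = ", ")))
    if (any(!is.finite(object@rates)) || any(object@rates < 0))
        return("all rates must be finite and >= 0")
    TRUE
})

#' Construct a RateModel
#'
#' @param model Model identifier: \code{"B1"}, \code{"B2"}, \code{"M1"}
#'   or \code{"M2"}.
#' @param ... Named rates, or a single named numeric vector. B1 takes
#'   \code{c}; B2 takes \code{g}, \code{l}; M1 takes \code{g1}, \code{g2},
#'   \code{l1}, \code{l2}, \code{c}; M2 takes \code{g1}, \code{g2},
#'   \code{l1}, \code{l2}, \code{c1}, \code{c2}.
#' @return A [RateModel-class] object.
#' @examples
#' RateModel("B2", g = 1, l = 3)
#' RateModel("M1", g1 = .5, g2 = 1, l1 = 1.5, l2 = 2, c = .2)
#' @export
RateModel <- function(model, ...) {
    if (length(model) != 1L || !model %in% names(.MODEL_PARAMS))
        stop("model must be one of B1, B2, M1, M2")
    dots <- list(...)
    if (length(dots) == 1L &&
        (is.null(names(dots)) || !any(nzchar(names(dots)))) &&
        length(dots[[1L]]) > 1L)
        rates <- unlist(dots[[1L]])
    else
        rates <- unlist(dots)
    if (!is.numeric(rates))
        stop("rates must be numeric")
    want <- .MODEL_PARAMS[[model]]
    if (is.null(names(rates)) || !setequal(names(rates), want) ||
        length(rates) != length(want))
        stop(sprintf("model %s requires rates named: %s", model,
                     paste(want, collapse = ", ")))
    new("RateModel", model = model, rates = rates[want])
}

#' @describeIn RateModel-class model identifier
#' @param object A \code{RateModel}.
#' @export
setMethod("modelId", "RateModel", function(object) object@model)

#' @describeIn RateModel-class named rate vector
#' @export
setMethod("rates", "RateModel", function(object) object@rates)

#' @describeIn RateModel-class number of free parameters (B1: 1, B2: 2,
#'   M1: 5, M2: 6) — the \code{p} entering the AIC.
#' @export
setMethod("nParams", "RateModel", function(object)
    length(.MODEL_PARAMS[[object@model]]))

#' @describeIn RateModel-class state labels, \code{c("0","1")} for binary
#'   models and \code{c("0","1","m")} for three-state models.
#' @export
setMethod("stateSpace", "RateModel", function(object)
    if (object@model %in% c("B1", "B2")) .BINARY_STATES else .TERNARY_STATES)

setMethod("show", "RateModel", function(object) {
    cat(sprintf("RateModel %s (%d states, p = %d)\n", object@model,
                length(stateSpace(object)), nParams(object)))
    print(signif(object@rates, 4))
})

#' Substitution-rate matrix Q of a model
#'
#' Builds the instantaneous rate matrix with off-diagonal entries given
#' by the model's rates and diagonal entries chosen so every row sums to
#' zero. Rows/columns are ordered (0, 1) for binary models and
#' (0, 1, m) for three-state models.
#'
#' @param object A [RateModel-class].
#' @param ... Unused.
#' @return A k x k numeric matrix with state labels as dimnames.
#' @examples
#' rateMatrix(RateModel("B1", c = 2))
#' @export
setMethod("rateMatrix", "RateModel", function(object, ...) {
    r <- object@rates
    Q <- switch(object@model,
        B1 = matrix(c(-r["c"], r["c"],
                       r["c"], -r["c"]), 2, 2, byrow = TRUE),
        B2 = matrix(c(-r["g"], r["g"],
                       r["l"], -r["l"]), 2, 2, byrow = TRUE),
        M1 = ,
        M2 = {
            if (object@model == "M1") {
                c1 <- r["c"]; c2 <- r["c"]
            } else {
                c1 <- r["c1"]; c2 <- r["c2"]
            }
            matrix(c(
                -(r["g1"] + c1), r["g1"],            c1,
                r["l1"], -(r["l1"] + r["g2"]),       r["g2"],
                c2,      r["l2"],      -(r["l2"] + c2)),
                3, 3, byrow = TRUE)
        })
    st <- stateSpace(object)
    dimnames(Q) <- list(st, st)
    Q
})

#' Transition-probability matrix P(t) = exp(Qt)
#'
#' Probabilities of moving between gene states along a branch of length
#' \code{t}, computed as the matrix exponential of \code{Q t}. Entries
#' are clamped to [0, 1] against roundoff; rows sum to 1 within 1e-10.
#'
#' @param object A [RateModel-class] or a square rate matrix with zero
#'   row sums.
#' @param t Branch length, a single nonnegative finite number.
#' @param ... Unused.
#' @return A k x k stochastic matrix.
#' @examples
#' transitionMatrix(RateModel("B2", g = 1, l = 3), 0.5)
#' @export
setMethod("transitionMatrix", "RateModel", function(object, t, ...)
    .expmQ(rateMatrix(object), t))

#' @rdname transitionMatrix-RateModel-method
#' @export
setMethod("transitionMatrix", "matrix", function(object, t, ...) {
    .checkRateMatrix(object)
    .expmQ(object, t)
})

.expmQ <- function(Q, t) {
    if (!is.numeric(t) || length(t) != 1L || !is.finite(t))
        stop("branch length t must be a single finite number")
    if (t < 0)
        stop("branch length t must be >= 0")
    if (t == 0 || all(Q == 0)) {
        P <- diag(nrow(Q))
        dimnames(P) <- dimnames(Q)
        return(P)
    }
    P <- as.matrix(Matrix::expm(Q * t))
    P[P < 0] <- 0
    P[P > 1] <- 1
    P <- P / rowSums(P)
    dimnames(P) <- dimnames(Q)
    P
}

.checkRateMatrix <- function(Q) {
    if (nrow(Q) != ncol(Q))
        stop("Q must be square")
    off <- Q; diag(off) <- 0
    if (any(off < 0))
        stop("off-diagonal rates must be >= 0")
    if (any(abs(rowSums(Q)) > 1e-8))
        stop("rows of Q must sum to 0")
    invisible(TRUE)
}

#' Analytic two-state transition probabilities
#'
#' Closed-form solution of the binary gain/loss chain, used as an
#' independent check on the matrix exponential:
#' p00 = (l + g e^{-(g+l)t}) / (g+l), p11 = (g + l e^{-(g+l)t}) / (g+l).
#'
#' @param g Gain rate (0 to 1), >= 0.
#' @param l Loss rate (1 to 0), >= 0.
#' @param t Branch length >= 0.
#' @return A 2 x 2 stochastic matrix over states ("0", "1"); the identity
#'   when \code{g = l = 0}.
#' @examples
#' twoStateClosedForm(1, 3, 0.5)
#' @export
twoStateClosedForm <- function(g, l, t) {
    stopifnot(is.numeric(g), is.numeric(l), is.numeric(t),
              g >= 0, l >= 0, t >= 0)
    if (g + l == 0) {
        P <- diag(2)
    } else {
        e <- exp(-(g + l) * t)
        p00 <- (l + g * e) / (g + l)
        p11 <- (g + l * e) / (g + l)
        P <- matrix(c(p00, 1 - p00, 1 - p11, p11), 2, 2, byrow = TRUE)
    }
    dimnames(P) <- list(.BINARY_STATES, .BINARY_STATES)
    P
}

#' Stationary distribution of a rate model
#'
#' Solves pi Q = 0 with sum(pi) = 1; this is the limit of the rows of
#' P(t) as t grows, for an irreducible chain.
#'
#' @param object A [RateModel-class] or a rate matrix.
#' @param ... Unused.
#' @return Named probability vector over the states.
#' @examples
#' stationaryDistribution(RateModel("B2", g = 1, l = 3))  # (0.75, 0.25)
#' @export
setMethod("stationaryDistribution", "RateModel", function(object, ...)
    .stationary(rateMatrix(object)))

#' @rdname stationaryDistribution-RateModel-method
#' @export
setMethod("stationaryDistribution", "matrix", function(object, ...) {
    .checkRateMatrix(object)
    .stationary(object)
})

.stationary <- function(Q) {
    k <- nrow(Q)
    if (all(Q == 0))
        stop("non-ergodic: zero rate matrix has no unique stationary ",
             "distribution")
    # solve t(Q) pi = 0 with the sum-to-one constraint appended
    A <- rbind(t(Q), rep(1, k))
    b <- c(rep(0, k), 1)
    pi <- tryCatch(as.vector(qr.solve(A, b)),
                   error = function(e) stop("non-ergodic rate matrix: ",
                                            conditionMessage(e)))
    if (max(abs(A %*% pi - b)) > 1e-8 || any(pi < -1e-9))
        stop("non-ergodic rate matrix: states do not all communicate")
    pi[pi < 0] <- 0
    pi <- pi / sum(pi)
    names(pi) <- rownames(Q)
    pi
}
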