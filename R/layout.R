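## Deterministic spring embedder. The declared force law (documented and
## relied on by the closed-form two-node test):
##   stress = sum over edges (d - k)^2  +  sum over node pairs with d < k of
##            (k - d)^2
## i.e. unit-length springs on edges plus soft-core pairwise repulsion with
## support radius k. Two connected nodes therefore equilibrate at distance
## exactly k. Optimization is damped gradient descent with per-node step
## capped by a temperature; a step is accepted only if the stress does not
## increase, otherwise the temperature is halved and the positions kept --
## so the recorded stress trace is non-increasing by construction and the
## result is a pure function of (graph, seed, maxIter).

.layoutStress <- function(pos, ei, ej, k) {
    s <- 0
    if (length(ei)) {
        d <- sqrt((pos[ei, 1] - pos[ej, 1])^2 + (pos[ei, 2] - pos[ej, 2])^2)
        s <- s + sum((d - k)^2)
    }
    n <- nrow(pos)
    if (n >= 2L) {
        dx <- outer(pos[, 1], pos[, 1], "-")
        dy <- outer(pos[, 2], pos[, 2], "-")
        d <- sqrt(dx^2 + dy^2)
        pen <- pmax(k - d, 0)^2
        s <- s + sum(pen[upper.tri(pen)])
    }
    s
}

.layoutGradientStep <- function(pos, ei, ej, k, step, temp) {
    n <- nrow(pos)
    force <- matrix(0, n, 2)
    eps <- 1e-12
    ## pairwise soft-core repulsion: magnitude 2(k - d) for d < k
    for (i in seq_len(n - 1L)) {
        for (j in seq((i + 1L), n)) {
            dx <- pos[i, 1] - pos[j, 1]
            dy <- pos[i, 2] - pos[j, 2]
            d <- sqrt(dx^2 + dy^2)
            if (d >= k) next
            if (d < eps) {   # coincident points: deterministic separation axis
                ang <- 2 * pi * (i * n + j) / (n * n + 1)
                dx <- cos(ang); dy <- sin(ang); d <- eps
            }
            f <- 2 * (k - d) / d
            force[i, ] <- force[i, ] + f * c(dx, dy)
            force[j, ] <- force[j, ] - f * c(dx, dy)
        }
    }
    ## edge springs: magnitude 2(d - k) toward the neighbor when stretched
    for (e in seq_along(ei)) {
        i <- ei[e]; j <- ej[e]
        dx <- pos[i, 1] - pos[j, 1]
        dy <- pos[i, 2] - pos[j, 2]
        d <- max(sqrt(dx^2 + dy^2), eps)
        f <- -2 * (d - k) / d
        force[i, ] <- force[i, ] + f * c(dx, dy)
        force[j, ] <- force[j, ] - f * c(dx, dy)
    }
    disp <- force * step
    len <- sqrt(rowSums(disp^2))
    over <- len > temp
    if (any(over))
        disp[over, ] <- disp[over, , drop = FALSE] * (temp / len[over])
    pos + disp
}

#' Deterministic force-directed layout
#'
#' Lays out an \code{\linkS4class{AnnotatedGraph}} with a spring embedder:
#' edges act as unit-length springs (rest length \code{springLength}) and all
#' node pairs repel within one spring length (soft-core repulsion), so nodes
#' spread out and chains stay chains. Optimization is damped gradient descent
#' with a temperature cap on per-node displacement; a step that would
#' increase the stress is rejected and the temperature halved, which makes
#' the stress trace non-increasing and the final stress no larger than that
#' of the random initialization. Identical \code{(g, seed, maxIter)} give
#' bit-identical positions; the global RNG state is left untouched.
#'
#' @param g A non-empty \code{\linkS4class{AnnotatedGraph}}.
#' @param seed Integer seed for the random initial positions.
#' @param maxIter Maximum number of epochs (>= 1).
#' @param springLength Rest length \code{k} of the edge springs (abstract
#'   canvas units); two connected nodes equilibrate at exactly this distance.
#' @param step Gradient step factor.
#' @param tol Convergence threshold on the largest per-node displacement.
#' @return A \code{\linkS4class{LayoutResult}}.
#' @examples
#' we <- makeWorkedExample()
#' g <- buildGraph(we$pathway, matchGuidelines(we$record, "clomipramine"),
#'                 variantCalls(we$record))
#' lay <- forceLayout(g, seed = 1)
#' head(positions(lay))
#' @export
forceLayout <- function(g, seed = 1L, maxIter = 600L, springLength = 1,
                        step = 0.05, tol = 1e-10) {
    stopifnot(is(g, "AnnotatedGraph"))
    if (maxIter < 1L) stop("maxIter must be >= 1", call. = FALSE)
    ids <- g@nodes$node_id
    n <- length(ids)
    if (n == 0L) stop("cannot lay out an empty graph", call. = FALSE)
    ei <- match(g@edges$from_id, ids)
    ej <- match(g@edges$to_id, ids)

    ## seed locally; restore the caller's RNG state
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    pos <- matrix(stats::runif(2L * n, 0, max(1, sqrt(n))), n, 2,
                  dimnames = list(ids, c("x", "y")))

    k <- springLength
    temp <- 0.5 * k
    stress <- .layoutStress(pos, ei, ej, k)
    trace <- numeric(maxIter + 1L)
    trace[1L] <- stress          # stress of the seeded random initialization
    iters <- 0L
    for (epoch in seq_len(maxIter)) {
        iters <- epoch
        cand <- .layoutGradientStep(pos, ei, ej, k, step, temp)
        candStress <- .layoutStress(cand, ei, ej, k)
        if (candStress <= stress) {
            moved <- max(sqrt(rowSums((cand - pos)^2)))
            pos <- cand
            stress <- candStress
            trace[epoch + 1L] <- stress
            if (moved < tol) break
        } else {
            temp <- temp / 2
            trace[epoch + 1L] <- stress
            if (temp < 1e-12) break
        }
    }
    new("LayoutResult", positions = pos, iterationsRun = iters,
        finalStress = stress, stressTrace = trace[seq_len(iters + 1L)],
        seed = as.integer(seed))
}
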