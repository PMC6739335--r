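# Synthetic network generation and case-study model loading.

#' Random Boolean network with a planted peelable chain
#'
#' Generates a seeded random network whose last `n_peelable` nodes form a
#' feed-forward chain ending in an outdegree-0 node, guaranteeing at least
#' `n_peelable` symmetric nodes under peeling. Core nodes draw their inputs
#' from the core only; with probability `p_deterministic` a core node gets
#' an indegree-1 copy/negation rule (seeding deterministic structure),
#' otherwise a random truth table at a random indegree up to `k_max`.
#'
#' @param n node count.
#' @param k_max maximum indegree (1 <= k_max < n).
#' @param p_deterministic probability of an indegree-1 copy/negation rule.
#' @param n_peelable length of the planted outdegree-0 chain
#'   (`n_peelable < n`).
#' @param seed RNG seed; the same spec and seed reproduce the network
#'   bit-exactly.
#' @return a `boolean_network` with nodes `x1 ... xn`.
#' @export
random_boolean_network <- function(n, k_max = 2L, p_deterministic = 0.3,
                                   n_peelable = 1L, seed = 1L) {
  if (n < 2L || k_max < 1L || k_max >= n || n_peelable >= n ||
      n_peelable < 0L) {
    stop("invalid generator spec", call. = FALSE)
  }
  with_seed(seed, {
    nodes <- paste0("x", seq_len(n))
    n_core <- n - n_peelable
    core <- seq_len(n_core)
    rules <- vector("list", n)
    for (i in core) {
      if (stats::runif(1) < p_deterministic) {
        inp <- sample(core, 1L)
        tab <- if (stats::runif(1) < 0.5) c(0L, 1L) else c(1L, 0L)
        rules[[i]] <- list(inputs = inp, table = tab)
      } else {
        k <- sample.int(min(k_max, n_core), 1L)
        inp <- sort(sample(core, k))
        tab <- sample(c(0L, 1L), 2^k, replace = TRUE)
        rules[[i]] <- list(inputs = inp, table = tab)
      }
    }
    if (n_peelable > 0L) {
      chain <- n_core + seq_len(n_peelable)
      for (j in seq_along(chain)) {
        # chain node j reads the next chain node; the last reads the core
        src <- if (j < n_peelable) chain[j + 1L] else sample(core, 1L)
        tab <- if (stats::runif(1) < 0.5) c(0L, 1L) else c(1L, 0L)
        rules[[chain[j]]] <- list(inputs = src, table = tab)
      }
    }
    names(rules) <- nodes
    boolean_network(nodes, rules)
  })
}

# clamp presets for the transcribed case-study models
.model_presets <- list(
  toy7 = list(file = "toy7_synthetic.bnet", clamps = NULL),
  CACC21 = list(file = "CACC21.bnet", clamps = NULL,
                source = "Supplementary Data 1 of the source publication"),
  CACC70 = list(file = "CACC70.bnet",
                clamps = c(DC = 1L, APC = 1L),
                source = "Supplementary Data 2 of the source publication"),
  Tcell60 = list(file = "Tcell60.bnet",
                 clamps = c(Stimuli = 1L, IL15 = 1L, PDGF = 1L,
                            CD45 = 0L, Stimuli2 = 0L, TAX = 0L),
                 source = "Supplementary Data 3 of the source publication"),
  MAPK53 = list(file = "MAPK53.bnet",
                clamps = c(EGFR = 1L),
                clamp_inputs_off = TRUE,
                source = "Supplementary Data 4 of the source publication")
)

#' Load a Boolean network model with its clamp preset
#'
#' Loads either an arbitrary rule file (by path) or one of the named
#' case-study models. The shipped `toy7` model is a synthetic
#' reconstruction of the published 7-node worked example (see the package
#' vignette); the larger case-study models are optional user transcriptions
#' of the publication's supplementary rule files, looked up under
#' `models_dir`. Clamp presets: CACC70 fixes DC=APC=1; Tcell60 fixes
#' Stimuli=IL15=PDGF=1 and CD45=Stimuli2=TAX=0; MAPK53 fixes EGFR=1 and all
#' input nodes (self-copy rules) to 0. Node names in clamp presets are
#' matched case-insensitively.
#'
#' @param name model name (`toy7`, `CACC21`, `CACC70`, `Tcell60`,
#'   `MAPK53`) or path to a rule file.
#' @param models_dir directory searched for named models (defaults to the
#'   installed package's `extdata/models`).
#' @return list with `network`, `clamps` (named 0/1 vector or NULL) and
#'   `name`.
#' @export
load_model <- function(name,
                       models_dir = system.file("extdata", "models",
                                                package = "brcnet")) {
  if (file.exists(name) && !dir.exists(name)) {
    return(list(network = parse_network(file = name), clamps = NULL,
                name = basename(name)))
  }
  preset <- .model_presets[[name]]
  if (is.null(preset)) {
    stop("unknown model '", name, "' and no such file; known models: ",
         paste(names(.model_presets), collapse = ", "), call. = FALSE)
  }
  path <- file.path(models_dir, preset$file)
  if (!file.exists(path)) {
    stop("model file ", preset$file, " not found under ", models_dir,
         ". Transcribe the update rules from ", preset$source,
         " into the rule dialect (one 'target, expression' line per node) ",
         "and place the file there.", call. = FALSE)
  }
  net <- parse_network(file = path)
  clamps <- preset$clamps
  if (!is.null(clamps)) {
    # tolerate case differences between figure labels and file spellings
    pos <- match(tolower(names(clamps)), tolower(net$nodes))
    if (anyNA(pos)) {
      stop("clamp preset node(s) missing from the model file: ",
           paste(names(clamps)[is.na(pos)], collapse = ", "), call. = FALSE)
    }
    names(clamps) <- net$nodes[pos]
  }
  if (isTRUE(preset$clamp_inputs_off)) {
    self_input <- vapply(seq_along(net$nodes), function(i) {
      r <- net$rules[[i]]
      length(r$inputs) == 1L && r$inputs == i && identical(r$table, c(0L, 1L))
    }, logical(1))
    inputs_off <- setdiff(net$nodes[self_input], names(clamps))
    clamps <- c(clamps, setNames(rep(0L, length(inputs_off)), inputs_off))
  }
  list(network = net, clamps = clamps, name = name)
}
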