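#' @useDynLib fusioncoal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim quantile dhyper rbinom pnorm median setNames runif
#' @importFrom utils read.table write.table
NULL

.TOPOLOGIES <- c("bifurcating", "introgression", "fusion")
.GENE_FLOWS <- c("none", "ancestral", "contemporary", "full")

#' Specify a demographic scenario
#'
#' A scenario is one of three three-deme topologies for the origin of the
#' putative hybrid deme (`alg`), crossed with one of four gene-flow
#' configurations. `bifurcating` is a strictly branching history in which
#' `alg` is sister to `sau`; `introgression` adds a post-divergence pulse of
#' gene flow from `bin` into `alg`; `fusion` derives `alg` from an admixture
#' event between the `bin` and `sau` ancestral lineages. Gene flow can be
#' absent, ancestral (a single symmetric rate between the two parental
#' lineages before their common-ancestor merge), contemporary (three pairwise
#' symmetric rates among the extant demes), or full (both).
#'
#' @param topology one of `"bifurcating"`, `"introgression"`, `"fusion"`.
#' @param gene_flow one of `"none"`, `"ancestral"`, `"contemporary"`, `"full"`.
#' @return an object of class `model_spec`.
#' @export
#' @examples
#' model_spec("fusion", "contemporary")
model_spec <- function(topology, gene_flow) {
  topology <- match.arg(topology, .TOPOLOGIES)
  gene_flow <- match.arg(gene_flow, .GENE_FLOWS)
  structure(list(topology = topology, gene_flow = gene_flow),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s topology, %s gene flow (k = %d)\n",
              x$topology, x$gene_flow, param_count(x)))
  invisible(x)
}

#' @export
format.model_spec <- function(x, ...) {
  paste0(x$topology, "+", x$gene_flow)
}

#' Enumerate the twelve competing demographic scenarios
#'
#' Returns the full 3 x 4 grid of topology by gene-flow configuration, in a
#' fixed order: topologies vary slowest (`bifurcating`, `introgression`,
#' `fusion`), gene flow fastest (`none`, `ancestral`, `contemporary`,
#' `full`).
#'
#' @return a list of 12 `model_spec` objects.
#' @export
enumerate_models <- function() {
  out <- vector("list", length(.TOPOLOGIES) * length(.GENE_FLOWS))
  i <- 1L
  for (top in .TOPOLOGIES) {
    for (gf in .GENE_FLOWS) {
      out[[i]] <- model_spec(top, gf)
      i <- i + 1L
    }
  }
  out
}

#' Names of the free parameters of a scenario
#'
#' The contemporary size of the `bin` deme is anchored externally (fixed from
#' nucleotide diversity via N_e = pi / (4 mu)) and is never free. In the
#' bifurcating and introgression topologies the `bin` branch keeps its
#' anchored size up to the deepest divergence, so no `N_anc_bin` parameter
#' exists there; the fusion topology frees the two parental sizes above the
#' admixture pulse.
#'
#' @param spec a `model_spec`.
#' @return character vector of free-parameter names.
#' @export
free_param_names <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  base <- switch(spec$topology,
    bifurcating = c("N_anc", "N_anc_sau", "N_sau", "N_alg",
                    "T_div1", "T_div2"),
    introgression = c("N_anc", "N_anc_sau", "N_sau", "N_alg",
                      "T_div1", "T_div2", "T_int", "gamma_int"),
    fusion = c("N_anc", "N_anc_sau", "N_anc_bin", "N_sau", "N_alg",
               "T_div1", "T_hyb", "gamma_hyb")
  )
  extra <- switch(spec$gene_flow,
    none = character(0),
    ancestral = "m_anc",
    contemporary = c("m_sau_alg", "m_bin_alg", "m_bin_sau"),
    full = c("m_sau_alg", "m_bin_alg", "m_bin_sau", "m_anc")
  )
  c(base, extra)
}

#' Number of free parameters of a scenario
#'
#' @param spec a `model_spec`.
#' @return integer count, excluding the fixed `bin` anchor size.
#' @export
#' @examples
#' param_count(model_spec("fusion", "contemporary"))  # 11
param_count <- function(spec) {
  length(free_param_names(spec))
}

#' Convert a time in generations to years
#'
#' The studied taxa are univoltine, so the default generation time is one
#' year and times in generations read directly as years.
#'
#' @param t_generations time in generations (non-negative).
#' @param generation_time_years generation time in years (positive).
#' @return time in years.
#' @export
time_in_years <- function(t_generations, generation_time_years = 1) {
  if (any(t_generations < 0)) stop("t_generations must be non-negative")
  if (any(generation_time_years <= 0)) {
    stop("generation_time_years must be positive")
  }
  t_generations * generation_time_years
}

.num_scalar <- function(x, name, lower = -Inf, strict_lower = FALSE) {
  if (is.null(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("parameter '%s' must be a finite numeric scalar", name))
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("parameter '%s' must be > %g", name, lower))
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("parameter '%s' must be >= %g", name, lower))
  }
  as.numeric(x)
}

#' Construct a fully parameterized demographic model
#'
#' Population sizes are absolute diploid effective sizes (the per-site
#' per-generation mutation rate `mu` is carried separately; mutation-scaled
#' theta = 4 N_e mu appears only at I/O boundaries). Times are in
#' generations before present; migration rates are per-generation backward
#' rates; admixture coefficients are the fraction of `alg` lineages tracing
#' to the `bin` side at the pulse.
#'
#' Parameters not used by `spec` are ignored; supplying a parameter the spec
#' requires as `NULL` is an error. Event-time ordering is enforced:
#' `0 < T_int < T_div2 < T_div1` for bifurcating/introgression topologies
#' (`T_int` only with introgression) and `0 < T_hyb < T_div1` for fusion.
#'
#' @param spec a `model_spec`.
#' @param N_bin anchored contemporary diploid size of the `bin` deme (fixed,
#'   not counted among free parameters).
#' @param N_sau,N_alg contemporary diploid sizes.
#' @param N_anc root ancestral diploid size.
#' @param N_anc_sau diploid size of the `sau`-side ancestor (`sau`+`alg`
#'   ancestor for bifurcating/introgression; the `sau` parental lineage above
#'   the pulse for fusion).
#' @param N_anc_bin diploid size of the `bin` parental lineage above the
#'   pulse (fusion only).
#' @param T_div1 deepest divergence time, generations.
#' @param T_div2 `alg`/`sau` divergence time (bifurcating/introgression).
#' @param T_hyb admixture (hybrid founding) time (fusion).
#' @param T_int introgression pulse time (introgression).
#' @param gamma_hyb,gamma_int admixture proportion in `[0, 1]`.
#' @param m_sau_alg,m_bin_alg,m_bin_sau contemporary symmetric pairwise
#'   migration rates per generation.
#' @param m_anc symmetric ancestral migration rate between the two parental
#'   lineages.
#' @param mu mutation rate per site per generation.
#' @param generation_time_years generation time (default 1; univoltine).
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(spec, N_bin, N_sau, N_alg, N_anc, N_anc_sau,
                              N_anc_bin = NULL, T_div1 = NULL, T_div2 = NULL,
                              T_hyb = NULL, T_int = NULL, gamma_hyb = NULL,
                              gamma_int = NULL, m_sau_alg = NULL,
                              m_bin_alg = NULL, m_bin_sau = NULL,
                              m_anc = NULL, mu = 2.8e-9,
                              generation_time_years = 1) {
  stopifnot(inherits(spec, "model_spec"))
  supplied <- list(
    N_bin = N_bin, N_sau = N_sau, N_alg = N_alg, N_anc = N_anc,
    N_anc_sau = N_anc_sau, N_anc_bin = N_anc_bin, T_div1 = T_div1,
    T_div2 = T_div2, T_hyb = T_hyb, T_int = T_int, gamma_hyb = gamma_hyb,
    gamma_int = gamma_int, m_sau_alg = m_sau_alg, m_bin_alg = m_bin_alg,
    m_bin_sau = m_bin_sau, m_anc = m_anc
  )
  needed <- c("N_bin", free_param_names(spec))
  params <- numeric(0)
  for (nm in needed) {
    x <- supplied[[nm]]
    # sizes and times strictly positive; migration rates and admixture
    # proportions may sit at zero (gamma at either boundary is meaningful)
    strict <- !startsWith(nm, "m_") && !startsWith(nm, "gamma")
    v <- .num_scalar(x, nm, lower = 0, strict_lower = strict)
    if (startsWith(nm, "gamma") && v > 1) {
      stop(sprintf("parameter '%s' must lie in [0, 1]", nm))
    }
    params[nm] <- v
  }
  # event ordering
  if (spec$topology == "fusion") {
    if (!(params["T_hyb"] < params["T_div1"])) {
      stop("event ordering violated: need 0 < T_hyb < T_div1")
    }
  } else {
    if (!(params["T_div2"] < params["T_div1"])) {
      stop("event ordering violated: need 0 < T_div2 < T_div1")
    }
    if (spec$topology == "introgression" &&
        !(params["T_int"] < params["T_div2"])) {
      stop("event ordering violated: need 0 < T_int < T_div2")
    }
  }
  mu <- .num_scalar(mu, "mu", lower = 0, strict_lower = TRUE)
  gt <- .num_scalar(generation_time_years, "generation_time_years",
                    lower = 0, strict_lower = TRUE)
  structure(list(spec = spec, params = params, mu = mu,
                 generation_time_years = gt),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("<demographic_model> %s\n", format(x$spec)))
  cat(sprintf("  mu = %g per site per generation, generation time = %g yr\n",
              x$mu, x$generation_time_years))
  for (nm in names(x$params)) {
    cat(sprintf("  %-10s %s%g\n", nm,
                if (nm == "N_bin") "(fixed) " else "", x$params[[nm]]))
  }
  invisible(x)
}

#' Mutation-scaled size of a deme
#'
#' theta = 4 N_e mu, the convention used when reporting sizes at I/O
#' boundaries.
#'
#' @param model a `demographic_model`.
#' @param param name of a size parameter (e.g. `"N_sau"`).
#' @return theta for that deme.
#' @export
theta_of <- function(model, param) {
  stopifnot(inherits(model, "demographic_model"))
  4 * model$params[[param]] * model$mu
}

#' Serialize / restore a demographic model configuration
#'
#' The configuration document mirrors the model fields: `topology`,
#' `gene_flow`, a `params` map of the free parameters plus the fixed
#' `N_bin` anchor, `mu` and `generation_time_years`. YAML or JSON is chosen
#' from the file extension (`.yaml`/`.yml` vs `.json`). Round-trips
#' losslessly.
#'
#' @param model a `demographic_model`.
#' @param path file path.
#' @return `read_model_config` returns a `demographic_model`;
#'   `write_model_config` returns `path` invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "demographic_model"))
  doc <- list(
    topology = model$spec$topology,
    gene_flow = model$spec$gene_flow,
    params = as.list(model$params),
    mu = model$mu,
    generation_time_years = model$generation_time_years
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path, precision = 17)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  req <- c("topology", "gene_flow", "params", "mu", "generation_time_years")
  if (!all(req %in% names(doc))) {
    stop("model config must contain fields: ", paste(req, collapse = ", "))
  }
  spec <- model_spec(doc$topology, doc$gene_flow)
  args <- c(list(spec = spec), doc$params,
            list(mu = doc$mu,
                 generation_time_years = doc$generation_time_years))
  do.call(demographic_model, args)
}
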