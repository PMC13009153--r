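## Conventions the implementation applies where printed criteria are
## internally inconsistent; attached to every stability report.
report_corrections <- function() {
  c(paste("flip criticality taken as R(-1) = 1 + trace + det = 0;",
          "the alternative printed condition equals R(1) = 0, which is",
          "r E gamma (alpha-gamma)^2/(alpha(alpha-gamma)) = 0 and",
          "unsatisfiable for r > 0"),
    paste("trivial fixed point classified from its exact multipliers",
          "{1 + r e, 1 - gamma}: a saddle for all r > 0, 0 < gamma < 2;",
          "the printed sink inequality r e (1-gamma) < gamma is exposed",
          "via origin_printed_condition() but never used"))
}

cplx_list <- function(z) list(re = Re(z), im = Im(z))

#' Assemble a stability report suitable for JSON serialization
#'
#' @param model a [ricker_holling()] model.
#' @param tol unit-circle tolerance for classification.
#' @return A nested list: parameters, one entry per fixed point with state,
#'   multipliers (re/im), jury values and classification, and the
#'   `corrections_applied` character vector.
#' @seealso [write_report_json()]
#' @export
stability_report <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "ricker_holling"))
  reps <- lapply(fixed_points(model), classify_fixed_point,
                 model = model, tol = tol)
  list(
    params = as.list(coef(model)),
    fixed_points = lapply(reps, function(rp) list(
      kind = rp$fixed_point$kind,
      state = as.list(rp$fixed_point$state),
      multipliers = lapply(as.list(rp$jac$multipliers), cplx_list),
      jury = rp$jury,
      classification = rp$classification)),
    tol = tol,
    corrections_applied = report_corrections())
}

## flip / ns analysis reports as plain lists ---------------------------------

flip_report <- function(alpha, gamma) {
  fa <- flip_analysis(alpha, gamma)
  list(params = list(alpha = alpha, gamma = gamma),
       r_c = fa$setup$r_c, rho2 = fa$setup$rho2,
       k1 = fa$k[["k1"]], k2 = fa$k[["k2"]],
       n = unlist(fa$nf[c("n1", "n2", "n3", "n4", "n5")]),
       w1 = fa$nf$w1, w2 = fa$nf$w2, verdict = fa$nf$verdict)
}

ns_report <- function(model) {
  nf <- ns_normal_form(model)
  list(params = as.list(coef(model)),
       rho = cplx_list(nf$linear$rho), modulus = nf$linear$modulus,
       transversality = nf$linear$dmod_deps,
       resonance_ok = nf$linear$resonance_ok,
       B = nf$B[grep("^B", names(nf$B))], A = nf$A,
       delta = lapply(nf$delta, cplx_list),
       chi = nf$chi, verdict = nf$verdict)
}

#' Write a report list as JSON
#'
#' @param report a list (e.g. from [stability_report()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write an orbit as CSV
#'
#' Columns `step`, `x`, `y`.
#'
#' @param orbit a `"ricker_holling_orbit"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_orbit_csv <- function(orbit, path) {
  write.csv(as.data.frame(orbit)[c("step", "x", "y")], path,
            row.names = FALSE)
  invisible(path)
}

#' Write a bifurcation diagram as CSV
#'
#' Long format: `r`, `sample_index`, `x`, `y`, `period`, `mle`.
#'
#' @param diagram a `"ricker_holling_diagram"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_diagram_csv <- function(diagram, path) {
  write.csv(as.data.frame(diagram), path, row.names = FALSE)
  invisible(path)
}

## CLI -----------------------------------------------------------------------

cli_usage <- function() {
  cat(
"usage: rickerpp <subcommand> [--flag value ...]

subcommands:
  simulate      orbit CSV          (--r --alpha --gamma | --scenario) [--x0 x,y]
                                   [--n 1000] [--transient 0] [--plot]
  fixed-points  fixed-point JSON   --alpha --gamma --r
  stability     stability JSON     --alpha --gamma --r
  flip          flip normal form   --alpha --gamma
  ns            NS normal form     --alpha --gamma --r
  diagram       sweep CSV          --alpha --gamma --r-min --r-max [--n-r]
                                   [--transient 1000] [--n-keep 200]
                                   [--cold-start] [--plot]
  lyapunov      MLE JSON           --alpha --gamma --r [--n 100000]
                                   [--transient 1000] [--seed 0]
  cascade       diagram + cascade  like `diagram`, also writes cascade JSON

common flags: --out DIR (default '.'), --config FILE (YAML; flags override),
              --scenario case1|case2|case3 (fills alpha/gamma/r/x0)
")
}

## "--key value" pairs (plus bare switches) -> named list of strings.
parse_cli_flags <- function(args) {
  out <- list()
  i <- 1L
  switches <- c("plot", "cold-start", "help")
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      abort_domain(sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3)
    if (key %in% switches) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args))
        abort_domain(sprintf("flag --%s needs a value", key))
      out[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  out
}

cli_num <- function(flags, key, default = NULL) {
  v <- flags[[key]]
  if (is.null(v)) {
    if (is.null(default))
      abort_domain(sprintf("missing required flag --%s", key))
    return(default)
  }
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) abort_domain(sprintf("flag --%s: '%s' is not a number", key, v))
  x
}

cli_model <- function(flags, need_r = TRUE) {
  if (!is.null(flags$scenario)) {
    sc <- rickerpp_scenario(flags$scenario)
    alpha <- cli_num(flags, "alpha", sc$alpha)
    gamma <- cli_num(flags, "gamma", sc$gamma)
    r <- cli_num(flags, "r", sc$r)
    x0 <- sc$x0
  } else {
    alpha <- cli_num(flags, "alpha")
    gamma <- cli_num(flags, "gamma")
    r <- if (need_r) cli_num(flags, "r") else cli_num(flags, "r", 1)
    x0 <- c(0.33, 0.64)
  }
  if (!is.null(flags$x0)) {
    x0 <- suppressWarnings(as.numeric(strsplit(flags$x0, ",")[[1]]))
    if (length(x0) != 2 || anyNA(x0))
      abort_domain("--x0 must be two comma-separated numbers, e.g. 0.33,0.64")
  }
  list(model = ricker_holling(r, alpha, gamma), alpha = alpha, gamma = gamma,
       r = r, x0 = x0)
}

#' Command-line interface
#'
#' Thin dispatcher over the package functions; see the `inst/cli/rickerpp.R`
#' script for shell use.  Writes CSV/JSON (and optional PNG) artifacts into
#' `--out` and logs the applied settings.  Domain errors (invalid or
#' non-positive parameters, no flip root, resonance, ...) exit with status
#' 2; success with 0.
#'
#' @param args character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly.
#' @examples
#' \donttest{
#' out <- tempdir()
#' run_cli(c("fixed-points", "--alpha", "2", "--gamma", "1",
#'           "--r", "3.598768", "--out", out))
#' }
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0 || args[[1]] %in% c("--help", "help")) {
      cli_usage()
      return(invisible(0L))
    }
    sub <- args[[1]]
    flags <- parse_cli_flags(args[-1])
    if (isTRUE(flags$help)) { cli_usage(); return(invisible(0L)) }
    if (!is.null(flags$config)) {
      cfg <- yaml::read_yaml(flags$config)
      cfg <- lapply(cfg, as.character)
      ## YAML 1.1 reads a bare `n` key as boolean FALSE; map it back
      names(cfg)[names(cfg) == "FALSE"] <- "n"
      for (k in names(cfg)) if (is.null(flags[[k]])) flags[[k]] <- cfg[[k]]
    }
    outdir <- if (is.null(flags$out)) "." else flags$out
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    cli_dispatch(sub, flags, outdir)
    0L
  },
  rickerpp_domain_error = function(e) {
    message("domain error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

cli_dispatch <- function(sub, flags, outdir) {
  art <- function(name) file.path(outdir, name)
  switch(sub,
    "simulate" = {
      mi <- cli_model(flags)
      n <- cli_num(flags, "n", 1000)
      tr <- cli_num(flags, "transient", 0)
      orb <- simulate(mi$model, nsim = n, x0 = mi$x0, transient = tr)
      write_orbit_csv(orb, art("orbit.csv"))
      if (isTRUE(flags$plot)) {
        png(art("phase_portrait.png"), 700, 700)
        plot(orb)
        dev.off()
      }
      message(sprintf(
        "simulate: r=%g alpha=%g gamma=%g x0=(%g,%g) n=%g transient=%g -> %s",
        mi$r, mi$alpha, mi$gamma, mi$x0[1], mi$x0[2], n, tr, art("orbit.csv")))
    },
    "fixed-points" = {
      mi <- cli_model(flags)
      fps <- fixed_points(mi$model)
      write_report_json(list(
        params = as.list(coef(mi$model)),
        fixed_points = lapply(fps, function(fp)
          list(kind = fp$kind, state = as.list(fp$state)))),
        art("fixed_points.json"))
      message("fixed-points -> ", art("fixed_points.json"))
    },
    "stability" = {
      mi <- cli_model(flags)
      write_report_json(stability_report(mi$model), art("stability.json"))
      message("stability -> ", art("stability.json"))
    },
    "flip" = {
      alpha <- cli_num(flags, "alpha"); gamma <- cli_num(flags, "gamma")
      write_report_json(flip_report(alpha, gamma), art("flip.json"))
      message("flip -> ", art("flip.json"))
    },
    "ns" = {
      mi <- cli_model(flags)
      write_report_json(ns_report(mi$model), art("ns.json"))
      message("ns -> ", art("ns.json"))
    },
    "diagram" = ,
    "cascade" = {
      mi <- cli_model(flags, need_r = FALSE)
      d <- bifurcation_sweep(
        mi$alpha, mi$gamma,
        r_min = cli_num(flags, "r-min"), r_max = cli_num(flags, "r-max"),
        n_r = { v <- cli_num(flags, "n-r", -1); if (v < 0) NULL else v },
        x0 = mi$x0,
        transient = cli_num(flags, "transient", 1000),
        n_keep = cli_num(flags, "n-keep", 200),
        warm_start = !isTRUE(flags[["cold-start"]]),
        seed = cli_num(flags, "seed", 0))
      write_diagram_csv(d, art("diagram.csv"))
      message("diagram -> ", art("diagram.csv"))
      if (sub == "cascade") {
        cs <- cascade_detect(d)
        write_report_json(list(
          params = list(alpha = mi$alpha, gamma = mi$gamma),
          onsets = cs), art("cascade.json"))
        message("cascade -> ", art("cascade.json"))
      }
      if (isTRUE(flags$plot)) {
        png(art("diagram.png"), 900, 700)
        plot(d)
        dev.off()
      }
    },
    "lyapunov" = {
      mi <- cli_model(flags)
      est <- max_lyapunov(mi$model, x0 = mi$x0,
                          n = cli_num(flags, "n", 1e5),
                          transient = cli_num(flags, "transient", 1000),
                          seed = cli_num(flags, "seed", 0))
      write_report_json(list(
        params = as.list(coef(mi$model)), mle = est$mle,
        n_steps = est$n_steps, transient = est$transient, seed = est$seed,
        diverged = if (is.na(est$diverged)) FALSE else est$diverged),
        art("lyapunov.json"))
      message("lyapunov -> ", art("lyapunov.json"))
    },
    abort_domain(sprintf("unknown subcommand '%s'", sub))
  )
}
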