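# Scenario configuration, presets and tabular output. Presets are data
# (JSON files under extdata/presets) so users can copy and edit them.

.presetDir <- function()
    system.file("extdata", "presets", package = "cellsizer", mustWork = TRUE)

#' List the shipped scenario presets
#'
#' Six presets cover the canonical mechanism combinations: `fig2a`
#' (adder + exponential), `fig2b` (adder + saturating), `fig2c`
#' (adder + decreasing/reciprocal), `fig3a` (adder + non-monotonic),
#' `fig3b` (sizer-adder mixture a = 0.6 + non-monotonic, extended grid),
#' `fig3c` (adder-timer mixture a = 1.5 + saturating). All share
#' `alpha = 1/48` per hour, `Vbar = 30`, `Tmin = 20` h, `Tf = 72` h.
#'
#' @return character vector of preset names.
#' @export
listPresets <- function()
    sort(sub("\\.json$", "", list.files(.presetDir(), pattern = "\\.json$")))

.configFieldError <- function(path, detail)
    stop(sprintf("config validation error at '%s': %s", path, detail),
         call. = FALSE)

.checkKeys <- function(x, allowed, path) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
        .configFieldError(paste0(path, ".", unknown[1]), "unknown key")
    invisible(x)
}

.requireKey <- function(x, key, path) {
    if (is.null(x[[key]]))
        .configFieldError(paste0(path, ".", key), "required field missing")
    x[[key]]
}

.validateScenarioConfig <- function(cfg) {
    if (!is.list(cfg)) .configFieldError("", "config must be a mapping")
    .checkKeys(cfg, c("name", "description", "law", "rule", "experiment",
                      "population"), "config")
    lawCfg <- .requireKey(cfg, "law", "config")
    .checkKeys(lawCfg, c("kind", "alpha", "Vth", "k"), "law")
    kind <- .requireKey(lawCfg, "kind", "law")
    if (!(kind %in% setdiff(.growthKinds, "custom")))
        .configFieldError("law.kind",
                          sprintf("'%s' is not a built-in growth law (one of %s)",
                                  kind,
                                  paste(setdiff(.growthKinds, "custom"),
                                        collapse = ", ")))
    ruleCfg <- .requireKey(cfg, "rule", "config")
    .checkKeys(ruleCfg, c("a", "Vbar", "Tmin"), "rule")
    .requireKey(ruleCfg, "a", "rule"); .requireKey(ruleCfg, "Vbar", "rule")
    expCfg <- .requireKey(cfg, "experiment", "config")
    .checkKeys(expCfg, c("Tf", "grid", "referenceSize"), "experiment")
    .requireKey(expCfg, "Tf", "experiment")
    if (!is.null(expCfg[["grid"]])) {
        .checkKeys(expCfg[["grid"]], c("lo", "hi", "n"), "experiment.grid")
        for (kk in c("lo", "hi", "n"))
            .requireKey(expCfg[["grid"]], kk, "experiment.grid")
    }
    if (!is.null(cfg[["population"]]))
        .checkKeys(cfg[["population"]],
                   c("nCells", "distribution", "meanSize", "cv", "nBins",
                     "binning", "seed"), "population")
    cfg
}

.lawFromConfig <- function(lawCfg)
    growthLaw(lawCfg[["kind"]], alpha = lawCfg[["alpha"]],
              Vth = if (is.null(lawCfg[["Vth"]])) NA_real_ else lawCfg[["Vth"]],
              k = if (is.null(lawCfg[["k"]])) NA_real_ else lawCfg[["k"]])

.ruleFromConfig <- function(ruleCfg)
    divisionRule(ruleCfg[["a"]], ruleCfg[["Vbar"]],
                 if (is.null(ruleCfg[["Tmin"]])) 0 else ruleCfg[["Tmin"]])

#' Load a scenario configuration
#'
#' Reads and validates a scenario from a shipped preset name (see
#' [listPresets()]) or a user JSON file with the same structure
#' (`law`, `rule`, `experiment`, optional `population` mappings).
#' Unknown keys are rejected with the offending field path.
#'
#' @param scenario preset name or path to a JSON config file.
#' @return the validated configuration as a named list.
#' @examples
#' cfg <- scenarioPreset("fig3a")
#' cfg[["law"]][["kind"]]
#' @export
scenarioPreset <- function(scenario) {
    path <- if (file.exists(scenario)) scenario
            else file.path(.presetDir(), paste0(scenario, ".json"))
    if (!file.exists(path))
        stop(sprintf(paste0("config validation error: '%s' is neither a ",
                            "preset (%s) nor an existing file"),
                     scenario, paste(listPresets(), collapse = ", ")),
             call. = FALSE)
    .validateScenarioConfig(jsonlite::read_json(path, simplifyVector = TRUE))
}

# full-precision CSV writer: numeric columns rendered with 17 significant
# digits so a re-read reproduces the doubles exactly
.writeCsvFull <- function(df, path) {
    out <- df
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
}

#' Write / read a capacity profile as CSV
#'
#' Columns `v0`, `capacity`, `v0_normalized`, `capacity_normalized`,
#' written with full double precision so that a re-read reproduces the
#' in-memory values exactly.
#'
#' @param profile a [Profile-class].
#' @param path CSV file path.
#' @return `writeProfileCsv` returns `path` invisibly; `readProfileCsv`
#'   returns the profile table as a data.frame.
#' @export
writeProfileCsv <- function(profile, path) {
    .writeCsvFull(profileTable(profile), path)
    invisible(path)
}

#' @rdname writeProfileCsv
#' @export
readProfileCsv <- function(path)
    utils::read.csv(path, colClasses = "numeric")

#' Classify the shape of a profile stored as CSV
#'
#' @param path CSV file written by [writeProfileCsv()] (or any CSV with a
#'   `capacity` column ordered by increasing size).
#' @param tol relative tolerance for [classifyShape()].
#' @return a shape label.
#' @export
classifyProfileFile <- function(path, tol = 1e-9) {
    df <- utils::read.csv(path)
    if (is.null(df$capacity))
        stop("config validation error: file has no 'capacity' column",
             call. = FALSE)
    classifyShape(df$capacity, tol)
}

#' Run a scenario end to end and write its outputs
#'
#' Loads a preset or config file, applies any overrides, computes the
#' capacity profile (and, when a `population` section is present, the
#' synthetic sorting assay), and writes into `outDir`:
#' `profile.csv`, `bins.csv` (population scenarios only),
#' `metadata.json` (all resolved parameters, seed, package version and
#' the shape label -- enough to re-run the scenario bit-identically) and
#' `run.log`. Partial outputs are removed on failure.
#'
#' @param scenario preset name or path to a JSON config file.
#' @param outDir output directory (created if needed).
#' @param tmin optional override for the minimum cycle duration (hours).
#' @param tf optional override for the culture horizon (hours).
#' @param grid optional override for the sweep grid, `c(lo, hi, n)`.
#' @param seed optional seed for the population stage.
#' @return invisibly, a list with elements `profile` (a
#'   [Profile-class]), `bins` (data.frame or `NULL`) and `paths`.
#' @examples
#' \donttest{
#' res <- runScenario("fig3a", tempfile("scenario"))
#' shapeLabel(res$profile)  # "unimodal"
#' }
#' @export
runScenario <- function(scenario, outDir, tmin = NULL, tf = NULL,
                        grid = NULL, seed = NULL) {
    cfg <- scenarioPreset(scenario)
    if (!is.null(tmin)) cfg[["rule"]][["Tmin"]] <- tmin
    if (!is.null(tf)) cfg[["experiment"]][["Tf"]] <- tf
    if (!is.null(grid)) {
        stopifnot(length(grid) == 3L)
        cfg[["experiment"]][["grid"]] <- list(lo = grid[1], hi = grid[2],
                                    n = as.integer(grid[3]))
    }
    if (!is.null(seed)) cfg[["population"]][["seed"]] <- seed
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(outDir, c(profile = "profile.csv",
                                 bins = "bins.csv",
                                 metadata = "metadata.json",
                                 log = "run.log"))
    names(paths) <- c("profile", "bins", "metadata", "log")
    written <- character(0)
    tryCatch({
        law <- .lawFromConfig(cfg[["law"]])
        rule <- .ruleFromConfig(cfg[["rule"]])
        g <- cfg[["experiment"]][["grid"]]
        logLines <- c(sprintf("scenario: %s",
                              if (is.null(cfg[["name"]])) scenario else cfg[["name"]]),
                      sprintf("law: %s", cfg[["law"]][["kind"]]),
                      sprintf("rule: a = %g (%s), Vbar = %g, Tmin = %g",
                              rule@a, strategyLabel(rule), rule@Vbar,
                              rule@Tmin),
                      sprintf("horizon: Tf = %g h", cfg[["experiment"]][["Tf"]]))
        profile <- computeProfile(
            rule, law, cfg[["experiment"]][["Tf"]],
            gridRange = if (is.null(g)) NULL else c(g[["lo"]], g[["hi"]]),
            gridPoints = if (is.null(g)) 200L else as.integer(g[["n"]]),
            referenceSize = cfg[["experiment"]][["referenceSize"]])
        writeProfileCsv(profile, paths[["profile"]])
        written <- c(written, paths[["profile"]])
        logLines <- c(logLines, sprintf("profile shape: %s", profile@shape))
        bins <- NULL
        if (!is.null(cfg[["population"]])) {
            p <- cfg[["population"]]
            sizes <- samplePopulation(
                nCells = .requireKey(p, "nCells", "population"),
                distribution = if (is.null(p[["distribution"]])) "lognormal"
                               else p[["distribution"]],
                meanSize = if (is.null(p[["meanSize"]])) rule@Vbar else p[["meanSize"]],
                cv = if (is.null(p[["cv"]])) 0.25 else p[["cv"]],
                seed = p[["seed"]])
            bins <- sortAndAssay(sizes, rule, law, cfg[["experiment"]][["Tf"]],
                                 nBins = if (is.null(p[["nBins"]])) 8L
                                         else as.integer(p[["nBins"]]),
                                 binning = if (is.null(p[["binning"]])) "quantile"
                                           else p[["binning"]])
            .writeCsvFull(bins, paths[["bins"]])
            written <- c(written, paths[["bins"]])
            logLines <- c(logLines, sprintf("population: %d cells, %d bins",
                                            length(sizes), nrow(bins)))
        }
        meta <- list(scenario = if (is.null(cfg[["name"]])) scenario else cfg[["name"]],
                     law = cfg[["law"]], rule = cfg[["rule"]],
                     experiment = cfg[["experiment"]],
                     population = cfg[["population"]],
                     shape = profile@shape,
                     seed = cfg[["population"]][["seed"]],
                     package_version =
                         as.character(utils::packageVersion("cellsizer")))
        jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE,
                             digits = NA, null = "null")
        written <- c(written, paths[["metadata"]])
        writeLines(logLines, paths[["log"]])
        invisible(list(profile = profile, bins = bins, paths = paths))
    }, error = function(e) {
        unlink(written)
        stop(e)
    })
}
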