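# shared fixtures: tiny cohorts and hand-built stride records, all generated
# in code at test time

tiny_cohort <- function(n = 8, seed = 101, ...) {
  simulate_cohort(sim_config(n_patients = n, seed = seed, ...))
}

# one-row event record with sensible defaults
make_event <- function(fs = 0, fo = 0.62, nfs = 1.0, stride_len = 1.2,
                       step_width = 0.1, leg = 0.9, height = 1.75) {
  tibble::tibble(
    foot_strike_s = fs, foot_off_s = fo, next_foot_strike_s = nfs,
    stride_length_m = stride_len, step_width_m = step_width,
    leg_length_m = leg, body_height_m = height
  )
}

# a perfectly symmetric stride pair: contralateral events offset by half a
# stride, identical timing otherwise
symmetric_pair <- function(stride_time = 1.0, stance = 0.62,
                           stride_len = 1.2) {
  ipsi <- make_event(0, stance * stride_time, stride_time, stride_len)
  contra <- make_event(0.5 * stride_time,
                       0.5 * stride_time + stance * stride_time,
                       1.5 * stride_time, stride_len)
  list(ipsi = ipsi, contra = contra)
}

# constant-valued 101 x 18 angle matrix
flat_angles <- function(value = 10) {
  matrix(value, 101, 18, dimnames = list(NULL, sms_angles()))
}

# a stub predictor returning a fixed sequence of outputs
registerS3method("predict", "const_model",
                 function(object, newdata, ...) {
                   rep_len(object$values, nrow(newdata))
                 },
                 envir = asNamespace("stats"))
const_model <- function(values) structure(list(values = values),
                                          class = "const_model")

# independent reference for the Alexander-Govern statistic via
# scipy.stats.alexandergovern (pre-installed python)
scipy_alexander_govern <- function(instances) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(instances, infile, digits = NA)
  script <- paste(
    "import json, sys",
    "from scipy.stats import alexandergovern",
    sprintf("data = json.load(open('%s'))", infile),
    "out = [{'statistic': float(alexandergovern(*g).statistic),",
    "        'p_value': float(alexandergovern(*g).pvalue)} for g in data]",
    sprintf("json.dump(out, open('%s', 'w'))", outfile),
    sep = "\n")
  status <- system2("python", "-", input = script)
  stopifnot(status == 0)
  jsonlite::read_json(outfile, simplifyVector = TRUE)
}

# independent ICC(1,1) via pingouin.intraclass_corr (pre-installed python)
pingouin_icc1 <- function(mat) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(mat, infile, digits = NA, matrix = "rowmajor")
  script <- paste(
    "import json, numpy as np, pandas as pd, pingouin as pg",
    sprintf("m = np.array(json.load(open('%s')))", infile),
    "n, k = m.shape",
    "df = pd.DataFrame({'targets': np.repeat(np.arange(n), k),",
    "                   'raters': np.tile(np.arange(k), n),",
    "                   'ratings': m.ravel()})",
    "icc = pg.intraclass_corr(df, targets='targets', raters='raters',",
    "                         ratings='ratings')",
    "val = float(icc.loc[icc['Type'].isin(['ICC1', 'ICC(1,1)']),",
    "                    'ICC'].iloc[0])",
    sprintf("json.dump(val, open('%s', 'w'))", outfile),
    sep = "\n")
  status <- system2("python", "-", input = script,
                    stderr = FALSE, stdout = FALSE)
  stopifnot(status == 0)
  jsonlite::read_json(outfile, simplifyVector = TRUE)
}
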