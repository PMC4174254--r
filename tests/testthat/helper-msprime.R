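# Independent coalescent oracle: msprime (via the python on PATH) run on
# three benchmark demographies that mirror configurations of the package's
# own simulator. Returns per-quantity means and standard errors computed
# from branch-mode statistics scaled by the mutation parameter, so both
# engines estimate the same expectations.
msprime_benchmarks <- function(n_reps = 10000, seed = 1) {
  script <- '
import sys, json, math
import numpy as np
import msprime

n_reps, seed, out = int(sys.argv[1]), int(sys.argv[2]), sys.argv[3]
MU = 0.0125  # expected mutations per generation of branch length

def run(demography, samples, rep_seed):
    tm, tl, dv = [], [], []
    reps = msprime.sim_ancestry(samples=samples, demography=demography,
                                ploidy=1, sequence_length=1,
                                num_replicates=n_reps,
                                random_seed=rep_seed)
    for ts in reps:
        tm.append(ts.max_root_time)
        tl.append(ts.segregating_sites(mode="branch"))
        dv.append(ts.diversity(mode="branch"))
    def ms(x):
        x = np.asarray(x, dtype=float)
        return [float(x.mean()), float(x.std(ddof=1) / math.sqrt(len(x)))]
    return {"tmrca": ms(tm), "S": ms(np.asarray(tl) * MU),
            "mpd": ms(np.asarray(dv) * MU)}

res = {}

d = msprime.Demography()
d.add_population(name="A", initial_size=1000)
res["constant"] = run(d, {"A": 10}, seed)

d = msprime.Demography()
g = math.log(10000 / 100) / 2000
d.add_population(name="A", initial_size=10000, growth_rate=g)
d.add_population_parameters_change(time=2000, population="A",
                                   initial_size=100, growth_rate=0)
res["bottleneck"] = run(d, {"A": 10}, seed + 1)

d = msprime.Demography()
d.add_population(name="A", initial_size=1000)
d.add_population(name="O", initial_size=800)
d.add_population(name="OOA", initial_size=500)
d.add_mass_migration(time=500, source="O", dest="OOA", proportion=1)
d.add_mass_migration(time=1000, source="OOA", dest="A", proportion=1)
res["split"] = run(d, {"A": 5, "O": 5}, seed + 2)

with open(out, "w") as fh:
    json.dump(res, fh)
'
  sf <- tempfile(fileext = ".py")
  out <- tempfile(fileext = ".json")
  writeLines(script, sf)
  status <- system2("python", c(sf, n_reps, seed, out),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(out)) {
    stop("msprime oracle failed: ", paste(status, collapse = "\n"))
  }
  jsonlite::read_json(out, simplifyVector = TRUE)
}

# The same three benchmark demographies expressed in the package's model.
benchmark_models <- function() {
  g <- 25
  bottleneck <- demographic_model(
    times = c(T1 = 2000, T2 = 1600, T3 = 1200, T4 = 800, T5 = 400,
              T6 = 200) * g,
    n_anc_africa = 100, n_ooa = 1000,
    n_anc = c(Oceania = 1000, Europe = 1000, `Central Asia` = 1000,
              `East Asia` = 1000, America = 1000),
    n_cur = c(Africa = 10000, Oceania = 1000, Europe = 1000,
              `Central Asia` = 1000, `East Asia` = 1000, America = 1000))
  split <- demographic_model(
    times = c(T1 = 4000, T2 = 1000, T3 = 500, T4 = 400, T5 = 300,
              T6 = 200) * g,
    n_anc_africa = 1000, n_ooa = 500,
    n_anc = c(Oceania = 800, Europe = 500, `Central Asia` = 500,
              `East Asia` = 500, America = 500),
    n_cur = c(Africa = 1000, Oceania = 800, Europe = 500,
              `Central Asia` = 500, `East Asia` = 500, America = 500))
  list(
    constant = list(model = const_model(1000),
                    cfg = sample_config(c(Africa = 10))),
    bottleneck = list(model = bottleneck,
                      cfg = sample_config(c(Africa = 10))),
    split = list(model = split,
                 cfg = sample_config(c(Africa = 5, Oceania = 5)))
  )
}
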