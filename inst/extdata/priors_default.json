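{
  "schema_version": "1.0",
  "recruitment": {
    "LS": [
      {
        "group": "2.5",
        "family": "gamma",
        "shape": 20,
        "rate": 10,
        "mean": 2
      },
      {
        "group": "3.5",
        "family": "gamma",
        "shape": 20,
        "rate": 10,
        "mean": 2
      },
      {
        "group": "4.5",
        "family": "gamma",
        "shape": 20,
        "rate": 10,
        "mean": 2
      },
      {
        "group": "5.5+",
        "family": "gamma",
        "shape": 16.4,
        "rate": 6,
        "mean": 2.74
      }
    ],
    "PR": [
      {
        "group": "2.5",
        "family": "beta",
        "alpha": 2.61,
        "beta": 1000,
        "mean": 0.003
      },
      {
        "group": "3.5",
        "family": "beta",
        "alpha": 34,
        "beta": 100,
        "mean": 0.25
      },
      {
        "group": "4.5",
        "family": "beta",
        "alpha": 54,
        "beta": 48,
        "mean": 0.53
      },
      {
        "group": "5.5+",
        "family": "beta",
        "alpha": 47,
        "beta": 50,
        "mean": 0.48
      }
    ],
    "SP": {
      "family": "beta",
      "alpha": 426,
      "beta": 500,
      "mean": 0.46
    }
  },
  "survival": {
    "HSm": {
      "family": "hierarchical-link-normal",
      "mean": 0.77,
      "long_term_precision": 3,
      "annual_precision_prior": {
        "shape": 20,
        "rate": 0.5
      },
      "link": "cloglog"
    },
    "HSf": {
      "family": "hierarchical-link-normal",
      "mean": 0.85,
      "long_term_precision": 3,
      "annual_precision_prior": {
        "shape": 20,
        "rate": 0.5
      },
      "link": "cloglog"
    },
    "NS": {
      "family": "hierarchical-link-normal",
      "mean": 0.95,
      "long_term_precision": 4,
      "annual_precision_prior": {
        "shape": 20,
        "rate": 0.5
      },
      "link": "cloglog"
    },
    "CubSa": {
      "family": "hierarchical-link-normal",
      "mean": 0.84,
      "long_term_precision": 4,
      "link": "cloglog"
    },
    "CubSb": {
      "family": "hierarchical-link-normal",
      "mean": 0.71,
      "long_term_precision": 4,
      "link": "cloglog"
    },
    "Rep": {
      "family": "hierarchical-link-normal",
      "mean": 0.98,
      "long_term_precision": 2,
      "link": "cloglog"
    }
  },
  "age_offsets": {
    "n_free": 3,
    "prior_sd": 1,
    "note": "cloglog-scale harvest-mortality offsets for age classes 1.5, 2.5, 3.5; 4.5+ is the reference (0)"
  },
  "initial_population": {
    "n_total": 21450,
    "dispersion": 0.15,
    "proportions_note": "synthetic stand-in: stable age-sex structure under the prior-mean vital rates, standing in for 30-year mean harvest proportions",
    "age_sex_proportions": {
      "F": [0.1062, 0.0854, 0.0686, 0.0552, 0.0443, 0.0356, 0.0287, 0.023, 0.0185, 0.0759],
      "M": [0.1247, 0.0908, 0.0661, 0.0481, 0.0351, 0.0255, 0.0186, 0.0135, 0.0099, 0.0263]
    }
  }
}
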