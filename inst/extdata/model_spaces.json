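{
  "naive_bayes": {
    "category": "nonlinear",
    "square_input": false,
    "space": {}
  },
  "random_forest": {
    "category": "nonlinear",
    "square_input": false,
    "space": {
      "estimators": {"lo": 50, "hi": 5000, "scale": "log", "type": "integer"},
      "max_nodes": {"lo": 5, "hi": 50, "scale": "uniform", "type": "integer"}
    }
  },
  "extra_trees": {
    "category": "nonlinear",
    "square_input": false,
    "space": {
      "estimators": {"lo": 50, "hi": 5000, "scale": "log", "type": "integer"},
      "max_nodes": {"lo": 5, "hi": 50, "scale": "uniform", "type": "integer"}
    }
  },
  "adaboost": {
    "category": "nonlinear",
    "square_input": false,
    "space": {
      "estimators": {"lo": 50, "hi": 5000, "scale": "log", "type": "integer"},
      "learning_rate": {"lo": 5, "hi": 50, "scale": "uniform", "type": "real"}
    }
  },
  "gradient_boosting": {
    "category": "nonlinear",
    "square_input": false,
    "space": {
      "estimators": {"lo": 50, "hi": 5000, "scale": "log", "type": "integer"},
      "learn_rate": {"lo": 0.1, "hi": 0.9, "scale": "uniform", "type": "real"},
      "max_depth": {"lo": 1, "hi": 10, "scale": "uniform", "type": "integer"},
      "subsample": {"lo": 0.2, "hi": 0.8, "scale": "uniform", "type": "real"},
      "colsample": {"lo": 0.2, "hi": 1.0, "scale": "uniform", "type": "real"}
    }
  },
  "svm_gaussian": {
    "category": "nonlinear",
    "square_input": false,
    "space": {
      "C": {"lo": 1e-4, "hi": 1e5, "scale": "log", "type": "real"},
      "max_iter": {"lo": 1e4, "hi": 1e5, "scale": "log", "type": "integer"},
      "gamma": {"lo": 1e-2, "hi": 1e2, "scale": "log", "type": "real"}
    }
  },
  "svm_linear": {
    "category": "linear",
    "square_input": false,
    "space": {
      "C": {"lo": 1e-4, "hi": 1e5, "scale": "log", "type": "real"},
      "max_iter": {"lo": 1e4, "hi": 1e5, "scale": "log", "type": "integer"}
    }
  },
  "logistic_lasso": {
    "category": "linear",
    "square_input": false,
    "space": {
      "C": {"lo": 1e-4, "hi": 1e4, "scale": "log", "type": "real"},
      "max_iter": {"lo": 1e4, "hi": 1e5, "scale": "log", "type": "integer"}
    }
  },
  "logistic_ridge": {
    "category": "linear",
    "square_input": false,
    "space": {
      "C": {"lo": 1e-4, "hi": 1e4, "scale": "log", "type": "real"},
      "max_iter": {"lo": 1e4, "hi": 1e5, "scale": "log", "type": "integer"}
    }
  },
  "dfnn": {
    "category": "deep",
    "square_input": false,
    "space": {
      "hidden_layers": {"lo": 1, "hi": 3, "scale": "uniform", "type": "integer"},
      "initial_width": {"lo": 16, "hi": 256, "scale": "uniform", "type": "integer"},
      "dropout": {"lo": 0.1, "hi": 0.6, "scale": "uniform", "type": "real"},
      "l2": {"lo": 1e-4, "hi": 2e-2, "scale": "log", "type": "real"}
    }
  },
  "lstm": {
    "category": "deep",
    "square_input": false,
    "space": {
      "hidden_layers": {"lo": 1, "hi": 3, "scale": "uniform", "type": "integer"},
      "initial_width": {"lo": 16, "hi": 256, "scale": "uniform", "type": "integer"},
      "dropout": {"lo": 0.1, "hi": 0.6, "scale": "uniform", "type": "real"},
      "l2": {"lo": 1e-4, "hi": 2e-2, "scale": "log", "type": "real"}
    }
  },
  "brainnet_cnn": {
    "category": "deep",
    "square_input": true,
    "space": {
      "hidden_layers": {"lo": 0, "hi": 2, "scale": "uniform", "type": "integer"},
      "initial_width": {"lo": 16, "hi": 64, "scale": "uniform", "type": "integer"},
      "dropout": {"lo": 0.1, "hi": 0.6, "scale": "uniform", "type": "real"},
      "leaky_slope": {"lo": 0.1, "hi": 0.5, "scale": "uniform", "type": "real"}
    }
  }
}
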