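{
  "nodes": [
    {
      "id": "Z1",
      "level": "organization",
      "kind": "continuous",
      "label": "intra-organizational networks",
      "dist": "normal"
    },
    {
      "id": "Z2",
      "level": "organization",
      "kind": "continuous",
      "label": "management style",
      "dist": "normal"
    },
    {
      "id": "Z3",
      "level": "organization",
      "kind": "continuous",
      "label": "organizational structure",
      "dist": "normal"
    },
    {
      "id": "B1",
      "level": "organization",
      "kind": "continuous",
      "label": "empirical evidence of effectiveness",
      "dist": "normal"
    },
    {
      "id": "W1",
      "level": "intervention",
      "kind": "continuous",
      "label": "anticipated cost, standard strategy",
      "dist": "normal"
    },
    {
      "id": "W2",
      "level": "intervention",
      "kind": "continuous",
      "label": "anticipated cost, enhanced strategy",
      "dist": "normal"
    },
    {
      "id": "W",
      "level": "intervention",
      "kind": "deterministic-aggregate",
      "label": "aggregate cost",
      "dist": "normal"
    },
    {
      "id": "D1",
      "level": "organization",
      "kind": "binary-decision",
      "label": "organization adopts CBT",
      "dist": "normal"
    },
    {
      "id": "D2",
      "level": "organization",
      "kind": "binary-decision",
      "label": "enhanced implementation strategy",
      "dist": "normal"
    },
    {
      "id": "X1",
      "level": "practitioner",
      "kind": "continuous",
      "label": "practitioner age",
      "dist": "normal"
    },
    {
      "id": "X2",
      "level": "practitioner",
      "kind": "continuous",
      "label": "perceived leadership",
      "dist": "normal"
    },
    {
      "id": "X3",
      "level": "practitioner",
      "kind": "continuous",
      "label": "tenure in current job",
      "dist": "normal"
    },
    {
      "id": "X4",
      "level": "practitioner",
      "kind": "continuous",
      "label": "perceived feasibility",
      "dist": "normal"
    },
    {
      "id": "X5",
      "level": "practitioner",
      "kind": "continuous",
      "label": "perceived appropriateness",
      "dist": "normal"
    },
    {
      "id": "V1",
      "level": "patient",
      "kind": "continuous",
      "label": "patient age",
      "dist": "normal"
    },
    {
      "id": "V2",
      "level": "patient",
      "kind": "continuous",
      "label": "patient gender",
      "dist": "bernoulli"
    },
    {
      "id": "V3",
      "level": "patient",
      "kind": "continuous",
      "label": "socio-economic status",
      "dist": "normal"
    },
    {
      "id": "Y1",
      "level": "patient",
      "kind": "continuous",
      "label": "baseline outcome score",
      "dist": "normal"
    },
    {
      "id": "T1",
      "level": "patient",
      "kind": "binary-decision",
      "label": "practitioner assigns treatment",
      "dist": "normal"
    },
    {
      "id": "Y2",
      "level": "patient",
      "kind": "continuous",
      "label": "follow-up outcome score",
      "dist": "normal"
    }
  ],
  "directed": [
    ["Z1", "D1"],
    ["Z2", "D1"],
    ["Z3", "D1"],
    ["B1", "D1"],
    ["W", "D1"],
    ["W1", "W"],
    ["W2", "W"],
    ["Z1", "D2"],
    ["Z2", "D2"],
    ["B1", "D2"],
    ["W1", "D2"],
    ["W2", "D2"],
    ["D2", "X4"],
    ["D2", "X5"],
    ["Z1", "X4"],
    ["Z1", "X5"],
    ["X1", "X4"],
    ["X1", "X5"],
    ["X2", "X4"],
    ["X2", "X5"],
    ["Z1", "T1"],
    ["X2", "T1"],
    ["X3", "T1"],
    ["X4", "T1"],
    ["X5", "T1"],
    ["V1", "T1"],
    ["V2", "T1"],
    ["Y1", "T1"],
    ["V3", "Y1"],
    ["T1", "Y2"],
    ["V1", "Y2"],
    ["V2", "Y2"],
    ["V3", "Y2"],
    ["Y1", "Y2"]
  ],
  "bidirected": [
    ["X2", "Z2"]
  ],
  "equations": [
    {
      "child": "W",
      "parents": ["W1", "W2"],
      "intercept": 0,
      "coefficients": [1, 1],
      "link": "deterministic-sum",
      "error_sd": 0
    },
    {
      "child": "D1",
      "parents": ["Z1", "Z2", "Z3", "B1", "W"],
      "intercept": 0,
      "coefficients": [0.4, 0.3, 0.3, 0.4, -0.3],
      "link": "latent-utility-threshold",
      "error_sd": 1
    },
    {
      "child": "D2",
      "parents": ["Z1", "Z2", "B1", "W1", "W2"],
      "intercept": 0,
      "coefficients": [0.3, 0.3, 0.3, 0.3, -0.3],
      "link": "latent-utility-threshold",
      "error_sd": 1
    },
    {
      "child": "X4",
      "parents": ["D2", "Z1", "X1", "X2"],
      "intercept": 0,
      "coefficients": [0.5, 0.3, 0.3, 0.3],
      "link": "linear",
      "error_sd": 1
    },
    {
      "child": "X5",
      "parents": ["D2", "Z1", "X1", "X2"],
      "intercept": 0,
      "coefficients": [0.5, 0.3, 0.3, 0.3],
      "link": "linear",
      "error_sd": 1
    },
    {
      "child": "Y1",
      "parents": "V3",
      "intercept": 0,
      "coefficients": 0.3,
      "link": "linear",
      "error_sd": 1
    },
    {
      "child": "T1",
      "parents": ["X4", "X5", "Z1", "X2", "X3", "V1", "V2", "Y1"],
      "intercept": 0,
      "coefficients": [0.4, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3],
      "link": "latent-utility-threshold",
      "error_sd": 1
    },
    {
      "child": "Y2",
      "parents": ["T1", "V1", "V2", "V3", "Y1"],
      "intercept": 0,
      "coefficients": [1, 0.3, 0.3, 0.3, 0.5],
      "link": "linear",
      "error_sd": 1
    }
  ],
  "correlated_errors": {
    "X2|Z2": 0.5
  },
  "hierarchy": {
    "organizations": 40,
    "practitioners_per_organization": 5,
    "patients_per_practitioner": 30
  },
  "selection_node": "D1"
}
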