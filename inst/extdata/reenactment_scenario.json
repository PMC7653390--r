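{
  "domain_bounds": {
    "kind": "rectangle",
    "vertices": [
      [0, 0],
      [3.55, 0],
      [3.55, 5.6],
      [0, 5.6]
    ]
  },
  "waiting_area": {
    "kind": "rectangle",
    "vertices": [
      [1, 2.3],
      [2.55, 2.3],
      [2.55, 4],
      [1, 4]
    ]
  },
  "source": {
    "kind": "rectangle",
    "vertices": [
      [1, 0],
      [2.55, 0],
      [2.55, 0.5],
      [1, 0.5]
    ]
  },
  "target": {
    "kind": "rectangle",
    "vertices": [
      [1, 4.7],
      [2.55, 4.7],
      [2.55, 5.55],
      [1, 5.55]
    ]
  },
  "obstacles": [
    {
      "kind": "rectangle",
      "vertices": [
        [0.15, 2],
        [0.85, 2],
        [0.85, 4.3],
        [0.15, 4.3]
      ]
    },
    {
      "kind": "rectangle",
      "vertices": [
        [2.7, 2],
        [3.4, 2],
        [3.4, 4.3],
        [2.7, 4.3]
      ]
    }
  ],
  "agents": [
    {
      "id": 1,
      "x": 1.775,
      "y": 0.25,
      "role": "walker",
      "free_flow_speed": 1.34
    },
    {
      "id": 2,
      "x": 1.0975,
      "y": 2.3975,
      "role": "waiter",
      "free_flow_speed": 1.34
    },
    {
      "id": 3,
      "x": 1.54916666666667,
      "y": 2.3975,
      "role": "waiter",
      "free_flow_speed": 1.34
    },
    {
      "id": 4,
      "x": 2.00083333333333,
      "y": 2.3975,
      "role": "waiter",
      "free_flow_speed": 1.34
    },
    {
      "id": 5,
      "x": 2.4525,
      "y": 2.3975,
      "role": "waiter",
      "free_flow_speed": 1.34
    },
    {
      "id": 6,
      "x": 1.32333333333333,
      "y": 2.89916666666667,
      "role": "waiter",
      "free_flow_speed": 1.34
    },
    {
      "id": 7,
      "x": 1.775,
      "y": 2.89916666666667,
      "role": "waiter",
      "free_flow_speed": 1.34
    },
    {
      "id": 8,
      "x": 2.22666666666667,
      "y": 2.89916666666667,
      "role": "waiter",
      "free_flow_speed": 1.34
    },
    {
      "id": 9,
      "x": 1.32333333333333,
      "y": 3.40083333333333,
      "role": "waiter",
      "free_flow_speed": 1.34
    },
    {
      "id": 10,
      "x": 1.775,
      "y": 3.40083333333333,
      "role": "waiter",
      "free_flow_speed": 1.34
    },
    {
      "id": 11,
      "x": 2.22666666666667,
      "y": 3.40083333333333,
      "role": "waiter",
      "free_flow_speed": 1.34
    },
    {
      "id": 12,
      "x": 1.32333333333333,
      "y": 3.9025,
      "role": "waiter",
      "free_flow_speed": 1.34
    },
    {
      "id": 13,
      "x": 1.775,
      "y": 3.9025,
      "role": "waiter",
      "free_flow_speed": 1.34
    },
    {
      "id": 14,
      "x": 2.22666666666667,
      "y": 3.9025,
      "role": "waiter",
      "free_flow_speed": 1.34
    }
  ],
  "params": {
    "dt": 0.6,
    "r": 1,
    "n_history": 3,
    "v_threshold": 0.2,
    "body_radius": 0.195,
    "v_free_mean": 1.34,
    "v_free_sd": 0.26,
    "swap_reach": 0.8,
    "t_max": 60,
    "seed": 1
  },
  "locomotion": {
    "w_target": 1,
    "w_agent": 0.08,
    "w_obstacle": 0.3,
    "range_agent": 0.3,
    "range_obstacle": 0.3
  }
}
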