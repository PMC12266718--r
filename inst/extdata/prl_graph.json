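{
  "schema_version": "1",
  "nodes": [
    {
      "base_name": "KeyPress",
      "node_type": "source",
      "outputs": ["Key Out"],
      "parameters": [{"name": "key", "value": "space", "updatable": false}],
      "worker_ref": "rigflow::worker_keypress"
    },
    {
      "base_name": "Trial Generator",
      "node_type": "transform",
      "inputs": ["Start/Previous Trial Result"],
      "outputs": ["Trial Definition"],
      "parameters": [
        {"name": "contingencies_block0", "value": [0.8, 0.8, 0.2, 0.2], "updatable": false},
        {"name": "contingencies_block1", "value": [0.2, 0.2, 0.8, 0.8], "updatable": false},
        {"name": "block_length_min", "value": 20, "updatable": false},
        {"name": "block_length_max", "value": 40, "updatable": false}
      ],
      "worker_ref": "rigflow::worker_trial_generator"
    },
    {
      "base_name": "Trial Controller",
      "node_type": "transform",
      "inputs": ["Trial Definition"],
      "outputs": ["Trial Result", "Trial History"],
      "parameters": [
        {"name": "odour_window", "value": 0.5, "updatable": true},
        {"name": "pre_response_delay", "value": 0.25, "updatable": true},
        {"name": "response_window", "value": 1.5, "updatable": true},
        {"name": "reward_window", "value": 1.0, "updatable": true},
        {"name": "reward_only_after_lick", "value": true, "updatable": true},
        {"name": "p_correct_lick", "value": 0.8, "updatable": true}
      ],
      "worker_ref": "rigflow::worker_trial_controller"
    },
    {
      "base_name": "Save Table",
      "node_type": "sink",
      "inputs": ["Row In"],
      "parameters": [],
      "worker_ref": "rigflow::worker_table_sink"
    }
  ],
  "edges": [
    {"from_node": "KeyPress##0", "from_output": "Key Out",
     "to_node": "Trial Generator##0", "to_input": "Start/Previous Trial Result"},
    {"from_node": "Trial Generator##0", "from_output": "Trial Definition",
     "to_node": "Trial Controller##0", "to_input": "Trial Definition"},
    {"from_node": "Trial Controller##0", "from_output": "Trial Result",
     "to_node": "Save Table##0", "to_input": "Row In"},
    {"from_node": "Trial Controller##0", "from_output": "Trial History",
     "to_node": "Trial Generator##0", "to_input": "Start/Previous Trial Result"}
  ]
}
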