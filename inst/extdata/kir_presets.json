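{
  "version": "1.0",
  "blockers": [
    {
      "id": "Mg",
      "z": 2,
      "kon0": 5000000,
      "delta_on": 0.08,
      "koff0": 4300,
      "zdelta_off": 0.48,
      "theta": 1.5089394,
      "vs": 4,
      "kexit0": 0,
      "zdelta_exit": 0
    },
    {
      "id": "SPM",
      "z": 4,
      "kon0": 10000000,
      "delta_on": 0.06,
      "koff0": 50,
      "zdelta_off": 2.32,
      "theta": 3.0123021,
      "vs": 4,
      "kexit0": 0.002,
      "zdelta_exit": 1
    }
  ],
  "genotypes": [
    {
      "name": "WT",
      "multipliers": []
    },
    {
      "name": "E224G",
      "multipliers": {
        "kon0": 0.24,
        "koff0": 0.086047,
        "zdelta_off": 1.1666667,
        "theta": 0.05
      }
    },
    {
      "name": "E224Q",
      "multipliers": {
        "kon0": 0.03,
        "koff0": 0.02,
        "theta": 0.05
      }
    },
    {
      "name": "E224A",
      "multipliers": {
        "kon0": 0.22,
        "koff0": 0.12,
        "theta": 0.06
      }
    },
    {
      "name": "E224C",
      "multipliers": {
        "kon0": 0.35,
        "koff0": 0.2,
        "theta": 0.06
      }
    },
    {
      "name": "E299S",
      "multipliers": {
        "kon0": 0.3,
        "koff0": 0.15,
        "theta": 0.06
      }
    },
    {
      "name": "E299A",
      "multipliers": {
        "kon0": 0.4,
        "koff0": 0.22,
        "theta": 0.07
      }
    },
    {
      "name": "E299C",
      "multipliers": {
        "kon0": 0.27,
        "koff0": 0.16,
        "theta": 0.06
      }
    },
    {
      "name": "M183W",
      "multipliers": {
        "kon0": 0.7,
        "koff0": 0.6511628,
        "zdelta_off": 0.9583333,
        "theta": 0.3
      }
    },
    {
      "name": "M183N",
      "multipliers": {
        "kon0": 0.4,
        "koff0": 1.2,
        "theta": 0.2
      }
    },
    {
      "name": "G177N",
      "multipliers": {
        "kon0": 0.5,
        "koff0": 1.5,
        "theta": 0.2
      }
    },
    {
      "name": "A178C",
      "multipliers": {
        "kon0": 0.45,
        "koff0": 1.1,
        "theta": 0.25
      }
    },
    {
      "name": "I176C",
      "multipliers": {
        "kon0": 0.55,
        "koff0": 1.4,
        "theta": 0.25
      }
    },
    {
      "name": "A181T",
      "multipliers": {
        "kon0": 0.6,
        "koff0": 1.2,
        "theta": 0.3
      }
    },
    {
      "name": "D172N",
      "multipliers": {
        "kon0": 0.8,
        "koff0": 1.6
      }
    },
    {
      "name": "A184Q",
      "multipliers": {
        "kon0": 0.9,
        "koff0": 1.35
      }
    },
    {
      "name": "E224G/M183W",
      "multipliers": {
        "kon0": 0.168,
        "koff0": 0.0534884,
        "zdelta_off": 1.2916667,
        "theta": 0.02
      }
    },
    {
      "name": "E224G/G177N",
      "multipliers": {
        "kon0": 0.12,
        "koff0": 12.90705,
        "zdelta_off": 1.1666667,
        "theta": 0.01
      }
    },
    {
      "name": "E224G/M183N",
      "multipliers": {
        "kon0": 0.096,
        "koff0": 6.195384,
        "zdelta_off": 1.1666667,
        "theta": 0.01
      }
    },
    {
      "name": "E224G/D172N",
      "multipliers": {
        "kon0": 0.192,
        "koff0": 0.1376752,
        "zdelta_off": 1.1666667,
        "theta": 0.05
      }
    },
    {
      "name": "E224G/A184Q",
      "multipliers": {
        "kon0": 0.216,
        "koff0": 0.11616345,
        "zdelta_off": 1.1666667,
        "theta": 0.05
      }
    },
    {
      "name": "E224Q/M183W",
      "multipliers": {
        "kon0": 0.15,
        "koff0": 0.1,
        "theta": 0.01
      }
    },
    {
      "name": "E224Q/M183N",
      "multipliers": {
        "kon0": 0.12,
        "koff0": 0.08,
        "theta": 0.01
      }
    },
    {
      "name": "E224Q/A178C",
      "multipliers": {
        "kon0": 0.1,
        "koff0": 0.06,
        "theta": 0.01
      }
    }
  ]
}
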