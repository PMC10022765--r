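{
  "name": "RQIT",
  "version": "1",
  "dimensions": [
    {
      "code": "A",
      "label": "Extent to which the question is important to patients and other health decision-makers",
      "levels": [
        {
          "code": "A1",
          "descriptor": "Not shown to be important to either patients or decision-makers"
        },
        {
          "code": "A2",
          "descriptor": "Shown to be important to health decision-makers but not patients"
        },
        {
          "code": "A3",
          "descriptor": "Shown to be important to patients but not decision-makers"
        },
        {
          "code": "A4",
          "descriptor": "Shown to be important to both patients and decision-makers"
        }
      ]
    },
    {
      "code": "B",
      "label": "That it addresses an area of high patient burden",
      "levels": [
        {
          "code": "B1",
          "descriptor": "Low patient burden"
        },
        {
          "code": "B2",
          "descriptor": "Medium patient burden"
        },
        {
          "code": "B3",
          "descriptor": "High patient burden"
        }
      ]
    },
    {
      "code": "C",
      "label": "That it addresses an area of high social burden",
      "levels": [
        {
          "code": "C1",
          "descriptor": "Condition is rare"
        },
        {
          "code": "C2",
          "descriptor": "Condition is somewhat common"
        },
        {
          "code": "C3",
          "descriptor": "Condition is common"
        },
        {
          "code": "C4",
          "descriptor": "Condition is highly prevalent"
        }
      ]
    },
    {
      "code": "D",
      "label": "Potential reduction in patient and/or social burden due to (clinical or implementation) intervention",
      "levels": [
        {
          "code": "D1",
          "descriptor": "Symptomatic treatment only and small potential effect size"
        },
        {
          "code": "D2",
          "descriptor": "Symptomatic treatment and large potential effect size"
        },
        {
          "code": "D3",
          "descriptor": "Potential for intervention to treat both symptoms and underlying disease pathology"
        },
        {
          "code": "D4",
          "descriptor": "Potential for cure or fundamental alteration of disease course"
        }
      ]
    },
    {
      "code": "E",
      "label": "Potential scalability and uptake of intervention",
      "levels": [
        {
          "code": "E1",
          "descriptor": "Low potential for scalability and uptake"
        },
        {
          "code": "E2",
          "descriptor": "High potential for uptake but low scalability"
        },
        {
          "code": "E3",
          "descriptor": "High potential for scalability but low potential for uptake"
        },
        {
          "code": "E4",
          "descriptor": "High potential for both scalability and uptake"
        }
      ]
    },
    {
      "code": "F",
      "label": "Extent to which the question addresses health equity",
      "levels": [
        {
          "code": "F1",
          "descriptor": "No information"
        },
        {
          "code": "F2",
          "descriptor": "Not relevant"
        },
        {
          "code": "F3",
          "descriptor": "Somewhat (may have some application to reduce health disparity)"
        },
        {
          "code": "F4",
          "descriptor": "Reducing health disparity is the focus"
        }
      ]
    }
  ]
}
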