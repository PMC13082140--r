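icd10,category,group
F20.0,Schizophrenia spectrum and other psychotic disorders,scz
F20.1,Schizophrenia spectrum and other psychotic disorders,scz
F20.2,Schizophrenia spectrum and other psychotic disorders,scz
F20.9,Schizophrenia spectrum and other psychotic disorders,scz
F21,Schizophrenia spectrum and other psychotic disorders,scz
F22,Schizophrenia spectrum and other psychotic disorders,scz
F23,Schizophrenia spectrum and other psychotic disorders,scz
F25.0,Schizophrenia spectrum and other psychotic disorders,scz
F25.1,Schizophrenia spectrum and other psychotic disorders,scz
F25.9,Schizophrenia spectrum and other psychotic disorders,scz
F28,Schizophrenia spectrum and other psychotic disorders,scz
F29,Schizophrenia spectrum and other psychotic disorders,scz
F40.00,Anxiety and fear-related disorders,control
F40.10,Anxiety and fear-related disorders,control
F41.0,Anxiety and fear-related disorders,control
F41.1,Anxiety and fear-related disorders,control
F41.9,Anxiety and fear-related disorders,control
F30.9,Bipolar and related disorders,control
F31.0,Bipolar and related disorders,control
F31.30,Bipolar and related disorders,control
F31.81,Bipolar and related disorders,control
F31.9,Bipolar and related disorders,control
F32.0,Depressive disorders,control
F32.1,Depressive disorders,control
F32.9,Depressive disorders,control
F33.0,Depressive disorders,control
F33.1,Depressive disorders,control
F33.2,Depressive disorders,control
F34.1,Depressive disorders,control
F43.0,Trauma- and stressor-related disorders,control
F43.10,Trauma- and stressor-related disorders,control
F43.12,Trauma- and stressor-related disorders,control
F43.21,Trauma- and stressor-related disorders,control
F43.23,Trauma- and stressor-related disorders,control
F43.9,Trauma- and stressor-related disorders,control
F10.10,Alcohol-related disorders,substance
F10.20,Alcohol-related disorders,substance
F10.929,Alcohol-related disorders,substance
F11.10,Opioid-related disorders,substance
F11.20,Opioid-related disorders,substance
F12.10,Cannabis-related disorders,substance
F12.20,Cannabis-related disorders,substance
F13.10,Sedative-related disorders,substance
F13.20,Sedative-related disorders,substance
F14.10,Stimulant-related disorders,substance
F14.20,Stimulant-related disorders,substance
F15.10,Stimulant-related disorders,substance
F16.10,Hallucinogen-related disorders,substance
F17.200,Tobacco-related disorders,substance
F17.210,Tobacco-related disorders,substance
F18.10,Inhalant-related disorders,substance
F19.10,Other specified substance-related disorders,substance
F19.20,Other specified substance-related disorders,substance
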