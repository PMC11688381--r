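# Anticoagulants and antiplatelets removed before top-N ranking:
# association with coagulopathy reports reflects indication, not signal.
# heparins
HEPARIN
ENOXAPARIN
DALTEPARIN
TINZAPARIN
NADROPARIN
FONDAPARINUX
# vitamin-K antagonists
WARFARIN
ACENOCOUMAROL
PHENPROCOUMON
FLUINDIONE
# direct oral anticoagulants
RIVAROXABAN
APIXABAN
EDOXABAN
BETRIXABAN
DABIGATRAN ETEXILATE
# direct thrombin / other parenteral
ARGATROBAN
BIVALIRUDIN
DESIRUDIN
# P2Y12 inhibitors
CLOPIDOGREL
PRASUGREL
TICAGRELOR
TICLOPIDINE
CANGRELOR
# other antiplatelets
ASPIRIN
DIPYRIDAMOLE
CILOSTAZOL
VORAPAXAR
# glycoprotein IIb/IIIa inhibitors
ABCIXIMAB
EPTIFIBATIDE
TIROFIBAN
# thrombolytics
ALTEPLASE
TENECTEPLASE
STREPTOKINASE
UROKINASE
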