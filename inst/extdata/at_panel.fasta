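>mal_1
HFSQVGMDQHHPVRCLKIATQKSFHMVCYSGHSQGCYGEFLAWSCCAMIGFPWLPHPINDDHTADYNNFHDFWCACIPGN
>mal_2
HFSQVGMDQSHPDRCLKIATQKSFHMVCYSGHSQGCMGEFLAWSCCAMIGFPWQPHPICDEHTYDVNNFHDFWCAAIPGN
>mal_3
HFSQVGMDQSHPDFCLKIATQKSFHMVCLSGHSQGCYGEFLAWSCCAMIRFPWKPHIINDEHTADVNNFHDFWCASIPGN
>mal_4
QFSQVGQDHSHPDRRLKIATQKSFHEVCYSGHSQGCYGEFLAWSCCAMIGFPWLPSPLNDEHTADVNNFHDFWCAAIPGN
>met_1
HFSLVDMDTSYPDECHKISTQKSFHMVCYTGHSQGCYGEDLKWSCCIIIGMNALAHPILDEHGMDVNNFHDFWRAARPGN
>met_2
HFSVVGMDTSYPDECMKISTLKSFHMVCYSGHSQGCYGGDLKWTCTIMFGMNALAHPITDEHGMDVFNFHDFWWAARPGN
>met_3
HFSLVGMDTSYPDECHKISTQKQFHMVCYDGHSQGCYGEDLKWSCCIHIGMNALAHPIRDEHGMDVNNFHDRWRAARPGN
>met_4
HFSLVGMDTSYRDECHKISTQKSFHMVCYSGHSQGCYGEDLKWICCIMIGMNALAYPIRDEHGMTVNNFHDFWRAAIPGN
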